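#' Published reference values used as generator ground truth
#'
#' Benchmark persistence lengths (nm), per-bp rises (nm), external charge
#' fractions (e per nucleotide) and related quantities for dsRNA and dsDNA
#' at the monovalent salt conditions the synthetic generators emulate.
#' Keys: \code{mt_*} single-molecule stretching values, \code{md_*}
#' simulation values, \code{rise_*} contour length per bp,
#' \code{intrinsic_*} the non-electrostatic (high-salt) limits,
#' \code{chargefrac_ext_*} external binding-ion charge fractions,
#' \code{pel_*}/\code{pnel_bj_*} electrostatic and BJ-fitted intrinsic
#' persistence lengths, and \code{n_bp_construct} the stretched construct
#' length in bp.
#'
#' @param key optional key; the full named list when omitted.
#' @return numeric value, or named list of all values.
#' @examples
#' referenceValues("md_rna_nacl_150mM")
#' @export
referenceValues <- function(key = NULL) {
  path <- system.file("extdata", "reference_values.json",
                      package = "helixbend")
  vals <- jsonlite::fromJSON(path)
  if (is.null(key)) return(vals)
  if (!key %in% names(vals)) stop("unknown reference key: ", key)
  vals[[key]]
}
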