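# End-to-end pipeline driver: chains the synthetic generators and every
# analysis stage and writes one CSV table per stage plus a JSON manifest.
# All randomness derives from the configuration seed, so identical
# configurations give byte-identical outputs.

#' Pipeline configuration
#'
#' Defaults reproduce the analysis settings used throughout the package:
#' 0.5 degree angle bins, 6 A external and 8.5 A helical cutoffs, 13/11 bp
#' segments with 3 terminal base pairs excluded, and the benchmark salt
#' conditions from [referenceValues()] as generator ground truth.  The
#' 1 M persistence lengths are interpolated between the 150 mM and 4 M
#' benchmarks with the BJ salt model (needed so the salt-fit stage has
#' three concentrations per molecule).
#'
#' @param outdir output directory for the stage tables.
#' @param seed master seed; every stage derives its own stream from it.
#' @param stages character vector of stages to run, a subset of
#'   c("fit_fx", "bend", "ions", "grooves", "decompose", "saltfit").
#' @param conditions data.frame with columns molecule, form, ion, conc_mM,
#'   P_mt, P_md, occ_external, rise; a default table is built from
#'   [referenceValues()].
#' @param n_molecules molecules per condition for the force-extension stage.
#' @param n_frames frames per condition for the trajectory stages.
#' @param n_bp base pairs per synthetic frame.
#' @param noise_x extension noise sigma in nm.
#' @param bin_deg angle-histogram bin width in degrees.
#' @param cutoff_ext,cutoff_helical ion-shell cutoffs in nm.
#' @param exclude_terminal terminal base pairs excluded from segments.
#' @return configuration list of class "helixbendPipelineConfig".
#' @export
pipelineConfig <- function(outdir = tempfile("helixbend_run_"), seed = 1,
                           stages = c("fit_fx", "bend", "ions", "grooves",
                                      "decompose", "saltfit"),
                           conditions = NULL, n_molecules = 10,
                           n_frames = 600, n_bp = 20, noise_x = 5,
                           bin_deg = 0.5, cutoff_ext = 0.6,
                           cutoff_helical = 0.85, exclude_terminal = 3) {
  if (is.null(conditions)) {
    rv <- referenceValues()
    bj_interp <- function(p150, p4M) {
      # BJ interpolation through the two benchmarks: P = P_nel + A kappa^-1
      k1 <- debyeLength(150); k2 <- debyeLength(4000)
      A <- (p150 - p4M) / (k1 - k2)
      function(c_mM) p4M + A * (debyeLength(c_mM) - k2)
    }
    prna <- bj_interp(rv$mt_rna_nacl_150mM, rv$mt_rna_nacl_4M)
    pdna <- bj_interp(rv$mt_dna_nacl_150mM, rv$mt_dna_nacl_4M)
    mrna <- bj_interp(rv$md_rna_nacl_150mM, rv$md_rna_nacl_4M)
    mdna <- bj_interp(rv$md_dna_nacl_150mM, rv$md_dna_nacl_4M)
    conditions <- data.frame(
      molecule = rep(c("dsRNA", "dsDNA"), each = 3),
      form = rep(c("A", "B"), each = 3),
      ion = "Na",
      conc_mM = rep(c(150, 1000, 4000), 2),
      P_mt = c(rv$mt_rna_nacl_150mM, prna(1000), rv$mt_rna_nacl_4M,
               rv$mt_dna_nacl_150mM, pdna(1000), rv$mt_dna_nacl_4M),
      P_md = c(rv$md_rna_nacl_150mM, mrna(1000), rv$md_rna_nacl_4M,
               rv$md_dna_nacl_150mM, mdna(1000), rv$md_dna_nacl_4M),
      occ_external = c(rv$chargefrac_ext_rna_nacl_150mM, 0.6,
                       rv$chargefrac_ext_rna_nacl_4M,
                       rv$chargefrac_ext_dna_nacl_150mM, 0.7,
                       rv$chargefrac_ext_dna_nacl_4M),
      rise = rep(c(rv$rise_rna, rv$rise_dna), each = 3))
  }
  cfg <- list(outdir = outdir, seed = seed, stages = stages,
              conditions = conditions, n_molecules = n_molecules,
              n_frames = n_frames, n_bp = n_bp, noise_x = noise_x,
              bin_deg = bin_deg, cutoff_ext = cutoff_ext,
              cutoff_helical = cutoff_helical,
              exclude_terminal = exclude_terminal)
  class(cfg) <- "helixbendPipelineConfig"
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates synthetic inputs per condition and runs the requested stages:
#' \describe{
#'   \item{fit_fx}{WLC fits of noisy force-extension curves, per molecule
#'     and aggregated per condition.}
#'   \item{bend}{segment bending-angle ensembles and persistence lengths
#'     from trajectory surrogates.}
#'   \item{ions}{binding-shell charge fractions per condition.}
#'   \item{grooves}{groove-width / inclination fluctuations and their
#'     Pearson correlations with the bending angle.}
#'   \item{decompose}{screened-Coulomb electrostatic bending-energy
#'     decomposition at 150 mM.}
#'   \item{saltfit}{OSF and BJ fits of the per-condition fitted P values.}
#' }
#' Each stage writes a CSV table into the output directory; a
#' \code{manifest.json} records every parameter.  Stage failures are
#' logged and dependent outputs skipped.
#'
#' @param config a [pipelineConfig()] list.
#' @return invisible list of the stage tables.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "helixbendPipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cond <- config$conditions
  out <- list()
  trajCache <- new.env(parent = emptyenv())

  getTraj <- function(i, with_ions) {
    key <- paste0(i, if (with_ions) "_ions" else "")
    if (!is.null(trajCache[[key]])) return(trajCache[[key]])
    gc_ <- generatorConfig(
      seed = config$seed * 1000 + i, n_frames = config$n_frames,
      n_bp = config$n_bp, form = cond$form[i], true_P = cond$P_md[i],
      occ_external = if (with_ions) cond$occ_external[i] else 0,
      bulk_mM = if (with_ions) min(cond$conc_mM[i], 300) else 0,
      ion_species = cond$ion[i])
    trajCache[[key]] <- sampleTrajectory(gc_)
    trajCache[[key]]
  }
  writeTab <- function(df, name) {
    utils::write.csv(df, file.path(config$outdir, paste0(name, ".csv")),
                     row.names = FALSE)
    df
  }
  tryStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      message("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
  }

  if ("fit_fx" %in% config$stages) {
    out$fit_fx <- tryStage("fit_fx", {
      rows <- list(); summ <- list()
      n_bp_mol <- referenceValues("n_bp_construct")
      for (i in seq_len(nrow(cond))) {
        fits <- lapply(seq_len(config$n_molecules), function(j) {
          cu <- synthForceExtension(
            P = cond$P_mt[i], Lc = cond$rise[i] * (n_bp_mol - 1),
            noise_x = config$noise_x,
            seed = config$seed * 10000 + i * 100 + j,
            molecule_id = sprintf("%s_mol%02d", cond$molecule[i], j),
            ion = cond$ion[i], conc_mM = cond$conc_mM[i])
          fitForceExtension(cu, n_bp = n_bp_mol)
        })
        rows[[i]] <- data.frame(
          molecule = cond$molecule[i], ion = cond$ion[i],
          conc_mM = cond$conc_mM[i],
          molecule_id = vapply(fits, function(x) x@molecule_id, ""),
          P = vapply(fits, function(x) x@P, 0),
          Lc = vapply(fits, function(x) x@Lc, 0),
          rise = vapply(fits, function(x) x@Lc / (n_bp_mol - 1), 0))
        agg <- aggregateCondition(fits)
        summ[[i]] <- data.frame(molecule = cond$molecule[i],
                                ion = cond$ion[i],
                                conc_mM = cond$conc_mM[i], agg)
      }
      writeTab(do.call(rbind, rows), "fit_fx_molecules")
      writeTab(do.call(rbind, summ), "fit_fx_summary")
    })
  }

  if ("bend" %in% config$stages) {
    out$bend <- tryStage("bend", {
      rows <- lapply(seq_len(nrow(cond)), function(i) {
        tr <- getTraj(i, with_ions = FALSE)
        ens <- collectSegments(tr, exclude_terminal = config$exclude_terminal)
        fit <- fitPFromPdf(angleHistogram(ens, config$bin_deg),
                           ens@segment_Lc)
        data.frame(molecule = cond$molecule[i], ion = cond$ion[i],
                   conc_mM = cond$conc_mM[i], P_md_true = cond$P_md[i],
                   P_fit = fit$P, se = fit$se,
                   segment_Lc = ens@segment_Lc,
                   n_angles = length(angles(ens)))
      })
      writeTab(do.call(rbind, rows), "bend_persistence")
    })
  }

  if ("ions" %in% config$stages) {
    out$ions <- tryStage("ions", {
      rows <- lapply(seq_len(nrow(cond)), function(i) {
        tr <- getTraj(i, with_ions = TRUE)
        cf <- chargeFractions(tr, config$cutoff_ext, config$cutoff_helical)
        data.frame(molecule = cond$molecule[i], ion = cond$ion[i],
                   conc_mM = cond$conc_mM[i], cf$summary)
      })
      writeTab(do.call(rbind, rows), "ion_charge_fractions")
    })
  }

  if ("grooves" %in% config$stages) {
    out$grooves <- tryStage("grooves", {
      rows <- list(); pccs <- list()
      for (i in seq_len(nrow(cond))) {
        tr <- getTraj(i, with_ions = FALSE)
        fg <- fluctuationProfile(tr, "total_groove_width")
        fi <- fluctuationProfile(tr, "inclination")
        rows[[i]] <- data.frame(
          molecule = cond$molecule[i], conc_mM = cond$conc_mM[i],
          groove_sd_per_nm = fg$mean, groove_block_sd = fg$block_sd,
          incl_sd_deg = fi$mean, incl_block_sd = fi$block_sd)
        pc <- correlateWithBend(tr, config$exclude_terminal,
                                observables = c("grooves", "inclination"))
        pccs[[i]] <- data.frame(molecule = cond$molecule[i],
                                conc_mM = cond$conc_mM[i], pc)
      }
      writeTab(do.call(rbind, rows), "groove_fluctuations")
      writeTab(do.call(rbind, pccs), "pearson_correlations")
    })
  }

  if ("decompose" %in% config$stages) {
    out$decompose <- tryStage("decompose", {
      rows <- lapply(which(cond$conc_mM == 150), function(i) {
        base <- makeIdealHelix(cond$form[i], config$n_bp)
        thetas <- seq(2, 40, by = 2)
        bent <- lapply(thetas, function(th) bendHelix(base, th))
        model <- electrostaticModel(cond$conc_mM[i])
        eel <- deltaEel(bent, base, model, theta_deg = thetas)
        # total bending energy on the same grid from the WLC form
        Lc <- (config$n_bp - 1) * base@form@rise_per_bp
        bend_prof <- data.frame(
          theta_deg = thetas,
          E_kBT = cond$P_md[i] * .deg2rad(thetas)^2 / (2 * Lc))
        dec <- decomposeBendingEnergy(bend_prof, eel, Lc)
        data.frame(molecule = cond$molecule[i], conc_mM = cond$conc_mM[i],
                   P = dec@P, P_el = dec@P_el, P_nel = dec@P_nel)
      })
      writeTab(do.call(rbind, rows), "energy_decomposition")
    })
  }

  if ("saltfit" %in% config$stages) {
    out$saltfit <- tryStage("saltfit", {
      src <- out$fit_fx
      rows <- lapply(unique(cond$molecule), function(mol) {
        sel <- cond$molecule == mol
        Pv <- if (!is.null(src)) {
          s <- src[src$molecule == mol & src$quantity == "P", ]
          s$mean[order(s$conc_mM)]
        } else cond$P_mt[sel][order(cond$conc_mM[sel])]
        ser <- saltSeries(sort(cond$conc_mM[sel]), Pv,
                          molecule = mol, ion = cond$ion[sel][1])
        do.call(rbind, lapply(c("BJ", "OSF"), function(mdl) {
          ft <- fitSaltSeries(ser, mdl)
          data.frame(molecule = mol, model = mdl, P_nel = ft@P_nel,
                     amplitude = ft@amplitude, rss = ft@rss)
        }))
      })
      writeTab(do.call(rbind, rows), "salt_model_fits")
    })
  }

  manifest <- list(package_version = as.character(utils::packageVersion("helixbend")),
                   seed = config$seed, n_molecules = config$n_molecules,
                   n_frames = config$n_frames, n_bp = config$n_bp,
                   noise_x = config$noise_x, bin_deg = config$bin_deg,
                   cutoff_ext = config$cutoff_ext,
                   cutoff_helical = config$cutoff_helical,
                   exclude_terminal = config$exclude_terminal,
                   stages = config$stages,
                   conditions = config$conditions)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
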