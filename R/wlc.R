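# Worm-like chain force-extension model and fitting.
#
# The force at fractional extension t = x/Lc is
#   F = kBT/P * [ 1/(4(1-t)^2) - 1/4 + t + sum_{i=2..7} alpha_i t^i ],
# the Marko-Siggia interpolation plus the seventh-order polynomial
# correction.  Fits are done on (x, log F), which weights the low-force
# part of the curve properly.

#' Evaluate the WLC force-extension relation
#'
#' @param P persistence length in nm.
#' @param Lc contour length in nm.
#' @param x extension(s) in nm, 0 <= x < Lc.
#' @param T temperature in K (kBT = 4.114 pN nm at 298 K, scaled linearly).
#' @param coeffs polynomial correction coefficients alpha_2..alpha_7; the
#'   default is [bouchiatCoefficients()].
#' @return force(s) in pN.
#' @examples
#' evalWlcForce(50, 4675, 2337.5)   # half extension
#' @export
evalWlcForce <- function(P, Lc, x, T = 298, coeffs = bouchiatCoefficients()) {
  if (P <= 0 || Lc <= 0) stop("P and Lc must be > 0")
  if (length(coeffs) != 6) stop("coeffs must supply alpha_2..alpha_7")
  if (any(x < 0) || any(x >= Lc)) stop("extension must satisfy 0 <= x < Lc")
  t <- x / Lc
  poly <- 0
  for (i in 2:7) poly <- poly + coeffs[[i - 1]] * t^i
  kBT(T) / P * (1 / (4 * (1 - t)^2) - 0.25 + t + poly)
}

# invert F(x) for one force by monotone root bracketing on x in [0, Lc)
.invertWlc <- function(F, P, Lc, T, coeffs, tol = 1e-12) {
  g <- function(x) evalWlcForce(P, Lc, x, T, coeffs) - F
  upper <- Lc * (1 - 1e-9)
  stats::uniroot(g, lower = 0, upper = upper, tol = tol * Lc)$root
}

#' Fit a force-extension curve with the WLC model
#'
#' Least-squares fit of \code{(x, log F)} to the WLC interpolation with
#' polynomial correction, the fitting variables being the persistence length
#' P and contour length Lc.  The contour length is constrained above the
#' largest observed extension.  Points whose extension reaches or exceeds
#' the running Lc bound are excluded with a warning.
#'
#' @param curve a [ForceExtensionCurve-class].
#' @param coeffs polynomial correction coefficients (default Bouchiat).
#' @param n_bp number of base pairs of the construct, if known; enables the
#'   per-bp rise report Lc/(n_bp - 1).
#' @param start optional named list with starting values \code{P}, \code{Lc}.
#' @return a [WLCFitResult-class].
#' @export
fitForceExtension <- function(curve, coeffs = bouchiatCoefficients(),
                              n_bp = NA_real_, start = NULL) {
  stopifnot(is(curve, "ForceExtensionCurve"))
  x <- curve@extension_nm
  F <- curve@force_pN
  T <- curve@temperature_K
  if (length(x) < 8)
    stop("insufficient data: need at least 8 force-extension points")
  if (max(F) / min(F) < 10)
    stop("insufficient data: forces must span at least a decade")
  Lc_lo <- max(x) * (1 + 1e-6)
  if (is.null(start)) start <- list(P = 50, Lc = 1.05 * max(x))
  start$Lc <- max(start$Lc, Lc_lo * 1.001)

  df <- data.frame(x = x, logF = log(F))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      logF ~ log(evalWlcForce(P, Lc, x, T = T, coeffs = coeffs)),
      data = df, start = start,
      lower = c(P = 0.1, Lc = Lc_lo), upper = c(P = 1e5, Lc = 1e9),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop("WLC fit failed to converge: ",
                             conditionMessage(e)))
  cf <- summary(fit)$coefficients
  new("WLCFitResult",
      P = cf["P", "Estimate"], Lc = cf["Lc", "Estimate"],
      se_P = cf["P", "Std. Error"], se_Lc = cf["Lc", "Std. Error"],
      rss = sum(stats::residuals(fit)^2), n_points = length(x),
      n_bp = n_bp, molecule_id = curve@molecule_id)
}

#' Aggregate WLC fits over molecules of one condition
#'
#' Repeated measurements on several molecules at one salt condition are
#' summarised by the mean, standard deviation and standard error of P and
#' Lc across molecules.
#'
#' @param results list of [WLCFitResult-class] objects.
#' @return data.frame with one row per quantity (P, Lc) and columns
#'   mean, sd, se, n.
#' @export
aggregateCondition <- function(results) {
  if (length(results) < 1) stop("need at least one fit result")
  stopifnot(all(vapply(results, is, TRUE, "WLCFitResult")))
  P <- vapply(results, function(r) r@P, 0)
  Lc <- vapply(results, function(r) r@Lc, 0)
  summ <- function(v) {
    s <- if (length(v) > 1) stats::sd(v) else 0
    c(mean = mean(v), sd = s, se = s / sqrt(length(v)), n = length(v))
  }
  out <- rbind(P = summ(P), Lc = summ(Lc))
  data.frame(quantity = rownames(out), out, row.names = NULL)
}
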