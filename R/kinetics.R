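#' Comparative-Ct (2^-ddCt) fold change
#'
#' `fold = 2^-((ct_target - ct_reference) - (ct_target_cal -
#' ct_reference_cal))`: the target gene's Ct is normalized to a reference
#' gene (e.g. ACTB) in both the sample of interest and a calibrator
#' sample.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest.
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator.
#' @return Fold change(s) relative to the calibrator.
#' @export
ddct_fold_change <- function(ct_target, ct_reference,
                             ct_target_cal, ct_reference_cal) {
  if (any(!is.finite(c(ct_target, ct_reference, ct_target_cal,
                       ct_reference_cal)))) {
    stop("all Ct values must be finite")
  }
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^(-ddct)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of `Ct = slope * log10(quantity) + intercept`
#' over a dilution series (>= 3 points). A valid curve has negative
#' slope (about -3.32 for perfect doubling efficiency).
#'
#' @param ct Ct values of the dilution series.
#' @param log10_quantity log10 relative input quantities.
#' @return A `StandardCurve`: list with `slope`, `intercept`,
#'   `r_squared`.
#' @export
fit_standard_curve <- function(ct, log10_quantity) {
  if (length(ct) != length(log10_quantity) || length(ct) < 3) {
    stop("need >= 3 dilution points")
  }
  fit <- stats::lm(ct ~ log10_quantity)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("invalid standard curve: slope must be negative")
  }
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    # suppressWarnings: summary.lm warns on numerically perfect fits
    r_squared = suppressWarnings(summary(fit)$r.squared)
  ), class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("StandardCurve: Ct = %.4f * log10(q) + %.4f (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert Ct values to percent remaining via a standard curve
#'
#' Inverts the curve to relative quantities and rescales so that the
#' reference Ct (typically the vehicle-treated sample) equals 100%.
#'
#' @param curve A `StandardCurve` from [fit_standard_curve()].
#' @param ct Ct value(s) to quantify.
#' @param reference_ct Ct of the 100% reference.
#' @return Percent-remaining value(s).
#' @export
quantify_percent <- function(curve, ct, reference_ct) {
  stopifnot(inherits(curve, "StandardCurve"))
  100 * 10^((ct - reference_ct) / curve$slope)
}

#' Fit one-phase exponential decay to an mRNA time course
#'
#' Least-squares fit of `N(t) = N0 * exp(-K * (t - t0))` with the plateau
#' fixed at 0 (complete decay) and `N0` free (initialized at 100 to
#' absorb normalization error); points before `t0` are excluded. The
#' half-life is `t_half = ln(2) / K`. When no decay signal is present
#' (fitted K below `k_tol`), `t_half` is reported as `Inf` and the
#' `has_decay` flag is `FALSE`. Setting `plateau = NULL` frees the
#' plateau as a third parameter.
#'
#' @param times Time points in hours.
#' @param percent Percent-remaining values (reference = 100).
#' @param t0 Time origin in hours (default 6, the first point at which
#'   decay is assumed to have started).
#' @param plateau Fixed plateau value (default 0); `NULL` to fit it.
#' @param k_tol Decay constants below this are treated as "no decay"
#'   (default 1e-8 per hour).
#' @return A `DecayFit`: list with `K` (1/h), `N0`, `t0`, `t_half` (h),
#'   `plateau`, `has_decay`.
#' @export
fit_decay <- function(times, percent, t0 = 6, plateau = 0, k_tol = 1e-8) {
  keep <- times >= t0
  t <- times[keep]; y <- percent[keep]
  if (length(t) < 3) stop("need >= 3 time points with t >= t0")
  # log-linear start values (guarding non-positive values)
  ypos <- pmax(y - if (is.null(plateau)) 0 else plateau, 1e-6)
  lf <- stats::lm(log(ypos) ~ I(t - t0))
  k0 <- max(-unname(stats::coef(lf)[2]), 1e-6)
  n0 <- min(exp(unname(stats::coef(lf)[1])), 1e4)
  fit <- if (is.null(plateau)) {
    minpack.lm::nlsLM(y ~ p + (N0 - p) * exp(-K * (t - t0)),
                      start = list(N0 = n0, K = k0, p = 0),
                      lower = c(N0 = 0, K = 0, p = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ plateau + (N0 - plateau) * exp(-K * (t - t0)),
                      start = list(N0 = n0, K = k0),
                      lower = c(N0 = 0, K = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  co <- stats::coef(fit)
  K <- unname(co["K"])
  has_decay <- is.finite(K) && K > k_tol
  structure(list(
    K = K,
    N0 = unname(co["N0"]),
    t0 = t0,
    t_half = if (has_decay) log(2) / K else Inf,
    plateau = if (is.null(plateau)) unname(co["p"]) else plateau,
    has_decay = has_decay
  ), class = "DecayFit")
}

#' @export
print.DecayFit <- function(x, ...) {
  if (x$has_decay) {
    cat(sprintf("DecayFit: K = %.5f /h, t1/2 = %.3f h (N0 = %.1f%%, t0 = %g h)\n",
                x$K, x$t_half, x$N0, x$t0))
  } else {
    cat("DecayFit: no decay signal (t1/2 not finite)\n")
  }
  invisible(x)
}
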