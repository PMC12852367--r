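#' Fit the aperiodic 1/f spectral slope
#'
#' Fits `log10(PSD) = offset - x * log10(f)` over the fit range (default
#' 1--45 Hz) with no knee ("fixed" aperiodic form). Narrow oscillatory
#' peaks are down-weighted by a single-pass robust refit: points more than
#' 2.5 residual SD above the initial fit are excluded once and the line is
#' refit. The spectral slope is `-x`; a flatter (less negative) slope
#' reads as a shift of excitation/inhibition balance toward excitation.
#'
#' @param ps a [welch_psd()] result
#' @param range fit range in Hz
#' @param peak_sd exclusion threshold in residual SDs
#' @return list of class `slope_fit` with `offset`, `exponent_x`, `slope`,
#'   `r_squared`, `n_points`, `fit_range`
#' @export
fit_spectral_slope <- function(ps, range = c(1, 45), peak_sd = 2.5) {
  stopifnot(inherits(ps, "power_spectrum"))
  sel <- ps$freqs >= range[1] - 1e-9 & ps$freqs <= range[2] + 1e-9 &
    ps$freqs > 0
  f <- ps$freqs[sel]
  p <- ps$psd[sel]
  if (length(f) < 10) stop("fewer than 10 spectral points in the fit range")
  if (any(p <= 0)) stop("non-positive PSD values in the fit range")
  lx <- log10(f)
  ly <- log10(p)
  fit <- stats::lm(ly ~ lx)
  res <- stats::resid(fit)
  keep <- res <= peak_sd * stats::sd(res)
  if (any(!keep) && sum(keep) >= 10) {
    fit <- stats::lm(ly[keep] ~ lx[keep])
  } else {
    keep <- rep(TRUE, length(lx))
  }
  cf <- stats::coef(fit)
  r2 <- summary(fit)$r.squared
  structure(list(offset = unname(cf[1]), exponent_x = unname(-cf[2]),
                 slope = unname(cf[2]), r_squared = r2,
                 n_points = sum(keep), fit_range = range),
            class = "slope_fit")
}

#' Average spectral slopes per subject and condition
#'
#' @param slope_table data frame with columns subject, condition, slope
#'   (one row per analysis interval)
#' @return data frame with per subject x condition mean slope and the
#'   number of intervals
#' @export
condition_average_slope <- function(slope_table) {
  stopifnot(all(c("subject", "condition", "slope") %in%
                  names(slope_table)))
  agg <- stats::aggregate(slope ~ subject + condition, slope_table, mean)
  cnt <- stats::aggregate(slope ~ subject + condition, slope_table, length)
  agg$n_intervals <- cnt$slope
  agg[order(agg$subject, agg$condition), ]
}

#' Regression of an outcome on spectral slope
#'
#' Ordinary least squares of `outcome` on `slope` over paired
#' observations; reports the raw coefficient B, the standardized beta,
#' its SE, t, p and R^2.
#'
#' @param slope numeric predictor (spectral slope)
#' @param outcome numeric outcome (e.g. spindle power)
#' @return list with `B`, `beta`, `SE`, `t`, `p`, `r_squared`, `n`
#' @export
slope_vs_outcome_regression <- function(slope, outcome) {
  ok <- stats::complete.cases(slope, outcome)
  x <- slope[ok]; y <- outcome[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  B <- unname(stats::coef(fit)[2])
  list(B = B,
       beta = B * stats::sd(x) / stats::sd(y),
       SE = sm$coefficients[2, 2],
       t = sm$coefficients[2, 3],
       p = sm$coefficients[2, 4],
       r_squared = sm$r.squared,
       n = length(x))
}
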