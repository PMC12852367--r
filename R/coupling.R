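# Complex-Morlet band transform: convolution with a Gaussian-envelope
# complex exponential centered on the band. For an in-band tone the
# argument equals the tone's instantaneous phase (negative-frequency
# leakage is negligible), so this serves as the analytic representation
# on epochs far shorter than an equivalent sharp FIR would need.
morlet_band <- function(x, fs, fc, sigma_t) {
  half_w <- min(ceiling(4 * sigma_t * fs), length(x) - 1L)
  tt <- (-half_w:half_w) / fs
  w <- exp(2i * pi * fc * tt) * exp(-tt^2 / (2 * sigma_t^2))
  w <- w / sum(Mod(w))
  n <- length(x)
  nf <- stats::nextn(n + 2L * half_w, 2)
  conv <- stats::fft(stats::fft(c(x, rep(0, nf - n))) *
                       stats::fft(c(w, rep(0, nf - length(w)))),
                     inverse = TRUE)[seq_len(n + 2L * half_w)] / nf
  conv[(half_w + 1):(half_w + n)]
}

#' Instantaneous SO phase of a trough-centered epoch
#'
#' Complex-wavelet transform of the epoch in the SO band; the phase is
#' mapped so that the positive peak of the SO waveform is 0 degrees and
#' phase increases along the falling flank (0 -> 90 -> 180 at the
#' trough -> 270 -> 360).
#'
#' @param epoch numeric 5-s epoch
#' @param fs sampling rate in Hz
#' @param band SO band in Hz (sets the wavelet center and bandwidth)
#' @return phase series in degrees `[0, 360)`
#' @export
so_phase_series <- function(epoch, fs, band = c(0.5, 1.25)) {
  x <- as.numeric(epoch)
  if (all(abs(x) < 1e-12)) stop("all-zero epoch: SO phase undefined")
  fc <- mean(band)
  sigma_f <- (band[2] - band[1]) / 4
  z <- morlet_band(x, fs, fc, sigma_t = 1 / (2 * pi * sigma_f))
  # scale by 2 to represent the analytic signal of a real input
  wrap_deg(rad2deg(Arg(2 * z)))
}

#' Instantaneous spindle-band amplitude of an epoch
#'
#' Magnitude of the analytic representation of the spindle-band filtered
#' signal (non-negative envelope, uV).
#'
#' @param epoch numeric epoch
#' @param fs sampling rate in Hz
#' @param band spindle band in Hz
#' @return envelope series in uV
#' @export
spindle_amplitude_series <- function(epoch, fs, band = c(12, 15)) {
  z <- band_analytic(as.numeric(epoch), fs, band[1], band[2],
                     trans_lo = 1, trans_hi = 1)
  Mod(z)
}

#' Event-locked SO-spindle phase-amplitude coupling
#'
#' For each trough-centered epoch: restrict the SO phase and spindle
#' envelope series to the analysis window (default -2 to 2 s around the
#' trough, avoiding filter edges), locate the spindle envelope maximum
#' (earliest sample on ties), and record the SO phase at that time -- one
#' spindle-at-peak phase per SO event. Epochs with undefined SO phase are
#' skipped.
#'
#' @param epochs list of 5-s epochs (as from [extract_event_epochs()])
#' @param fs sampling rate in Hz
#' @param so_band,spindle_band filter bands in Hz
#' @param window analysis window in seconds relative to the trough
#' @param subject,condition labels attached to the distribution
#' @return object of class `coupling_distribution`: data frame `phases`
#'   (degrees), `subject`, `condition`, `n_skipped`
#' @export
event_locked_pac <- function(epochs, fs, so_band = c(0.5, 1.25),
                             spindle_band = c(12, 15),
                             window = c(-2, 2),
                             subject = NA_character_,
                             condition = NA_character_) {
  if (length(epochs) == 0) stop("no epochs supplied")
  phases <- numeric(0)
  skipped <- 0L
  for (ep in epochs) {
    x <- as.numeric(ep)
    half <- (length(x) - 1) / (2 * fs)
    tt <- (seq_along(x) - 1) / fs - half
    ph <- tryCatch(so_phase_series(x, fs, so_band), error = function(e) NULL)
    if (is.null(ph)) {
      skipped <- skipped + 1L
      next
    }
    env <- spindle_amplitude_series(x, fs, spindle_band)
    sel <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
    i_max <- which(sel)[which.max(env[sel])]
    phases <- c(phases, ph[i_max])
  }
  structure(list(phases = phases, subject = subject, condition = condition,
                 n_skipped = skipped),
            class = "coupling_distribution")
}

circ_R <- function(phases_deg) {
  if (length(phases_deg) == 0) return(NA_real_)
  a <- deg2rad(phases_deg)
  sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

circ_mean_deg <- function(phases_deg) {
  a <- deg2rad(phases_deg)
  wrap_deg(rad2deg(atan2(mean(sin(a)), mean(cos(a)))))
}

#' Circular summary of a coupling distribution
#'
#' Mean coupling phase angle (atan2 of the mean sine and cosine) and the
#' coupling strength R (resultant vector length, 0 = uniform, 1 = all
#' phases identical). The mean angle is flagged undefined (NA) when R is
#' numerically zero.
#'
#' @param dist a `coupling_distribution` or numeric phase vector (degrees)
#' @return list with `mean_angle` (degrees), `R`, `n_events`
#' @export
circular_summary <- function(dist) {
  phases <- if (inherits(dist, "coupling_distribution")) dist$phases else
    as.numeric(dist)
  n <- length(phases)
  if (n == 0) stop("empty phase distribution")
  R <- circ_R(phases)
  mean_angle <- if (R < 1e-12) NA_real_ else circ_mean_deg(phases)
  list(mean_angle = mean_angle, R = R, n_events = n)
}

# Fisher's approximation of the inverse of A(kappa) = I1/I0.
kappa_from_rbar <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equal mean directions
#'
#' Circular one-way comparison of k groups of angles with the standard
#' concentration correction factor `1 + 3/(8*kappa)`; the statistic is
#' referred to an F distribution with (k-1, N-k) degrees of freedom. A
#' warning flag is set when the pooled concentration is low (mean
#' resultant length below ~0.45), where the test is only approximate.
#'
#' @param groups list of numeric phase vectors in degrees (each n >= 5)
#' @return list with `F`, `df1`, `df2`, `p`, `kappa`, `low_concentration`
#' @export
watson_williams <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  ns <- lengths(groups)
  if (any(ns < 5)) stop("each group needs at least 5 angles")
  N <- sum(ns)
  Ri <- vapply(seq_len(k), function(i) length(groups[[i]]) *
                 circ_R(groups[[i]]), numeric(1))
  Rall <- N * circ_R(unlist(groups))
  rw <- sum(Ri) / N
  kap <- kappa_from_rbar(rw)
  low <- rw < 0.45
  if (low) warning("low concentration: Watson-Williams approximation weak")
  g <- 1 + 3 / (8 * kap)
  Fstat <- g * ((N - k) * (sum(Ri) - Rall)) / ((k - 1) * (N - sum(Ri)))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  list(F = Fstat, df1 = k - 1, df2 = N - k, p = p, kappa = kap,
       low_concentration = low)
}
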