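#' @useDynLib sleeposc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft nextn spline rnorm runif rpois quantile sd var
#'   coef lm pf pt pnorm anova qnorm cor.test complete.cases median
#'   p.adjust t.test setNames aggregate approx
#' @importFrom utils head tail write.csv read.csv
NULL

# Linear convolution via FFT; returns full length(x)+length(h)-1 result.
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, rep(0, nf - length(x))))
  hf <- stats::fft(c(h, rep(0, nf - length(h))))
  Re(stats::fft(xf * hf, inverse = TRUE))[seq_len(n)] / nf
}

# Zero-phase FIR filtering: centered convolution so the output aligns with
# the input sample-for-sample. Taps must be odd-length and symmetric.
filt_zero_phase <- function(x, h) {
  stopifnot(length(h) %% 2L == 1L)
  m <- (length(h) - 1L) / 2L
  fft_conv(x, h)[(m + 1L):(m + length(x))]
}

# Windowed-sinc (Hamming) lowpass prototype, unit DC gain.
fir_lowpass <- function(fc, fs, ntaps) {
  stopifnot(ntaps %% 2L == 1L, fc > 0, fc < fs / 2)
  t <- (0:(ntaps - 1L)) - (ntaps - 1L) / 2
  h <- ifelse(t == 0, 2 * fc / fs, sin(2 * pi * fc / fs * t) / (pi * t))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(ntaps - 1L)) / (ntaps - 1L))
  h <- h * w
  h / sum(h)
}

# Bandpass by spectral inversion of two lowpass prototypes. The number of
# taps is set from the narrower transition width (Hamming: ~3.3/N cycles).
fir_bandpass <- function(lo, hi, fs, trans_lo = 0.1, trans_hi = 0.5) {
  stopifnot(lo > 0, hi > lo, hi < fs / 2)
  width <- min(trans_lo, trans_hi) / fs
  ntaps <- ceiling(3.3 / width)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  h_hi <- fir_lowpass(hi, fs, ntaps)
  h_lo <- fir_lowpass(lo, fs, ntaps)
  h <- h_hi - h_lo
  h
}

# Analytic signal via frequency-domain construction (one-sided spectrum).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  hmul <- numeric(n)
  if (n %% 2L == 0L) {
    hmul[c(1L, n / 2L + 1L)] <- 1
    hmul[2:(n / 2L)] <- 2
  } else {
    hmul[1L] <- 1
    hmul[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * hmul, inverse = TRUE) / n
}

# Band-pass + analytic representation; shared by the coupling module.
band_analytic <- function(x, fs, lo, hi, trans_lo = 0.2, trans_hi = 1) {
  h <- fir_bandpass(lo, hi, fs, trans_lo, trans_hi)
  if (length(h) > 4L * length(x)) {
    stop("signal too short for the requested band-pass filter")
  }
  analytic_signal(filt_zero_phase(x, h))
}

wrap_deg <- function(x) ((x %% 360) + 360) %% 360

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Smallest signed circular difference a - b in degrees, in (-180, 180].
circ_diff_deg <- function(a, b) {
  d <- wrap_deg(a - b)
  ifelse(d > 180, d - 360, d)
}
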