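#' Morlet time-frequency map of one SO epoch
#'
#' Complex-Morlet (fixed 5 cycles) power on a 10--20 Hz grid in 0.2 Hz
#' steps, computed after downsampling the 5-s trough-centered epoch to
#' 50 Hz. The first and last 150 ms are trimmed to remove wavelet edge
#' effects, leaving times spanning about -2.35 to +2.35 s.
#'
#' @param epoch numeric 5-s epoch (trough at the center)
#' @param fs_in sampling rate of the epoch in Hz
#' @param target_fs analysis rate in Hz
#' @param n_cycles wavelet cycles
#' @param freqs frequency grid in Hz
#' @param trim seconds trimmed from each end
#' @return object of class `tfr_map`: `times` (s, trough at 0), `freqs`
#'   (Hz), `power` (time x frequency, uV^2), `baseline_state`
#' @export
morlet_tfr <- function(epoch, fs_in, target_fs = 50, n_cycles = 5,
                       freqs = seq(10, 20, by = 0.2), trim = 0.15) {
  x <- as.numeric(epoch)
  half <- (length(x) - 1) / (2 * fs_in)
  if (length(x) / fs_in < n_cycles / min(freqs) + 2 * trim) {
    stop("epoch shorter than the wavelet support at the lowest frequency")
  }
  if (target_fs < fs_in) x <- resample_signal(x, fs_in, target_fs)
  fs <- target_fs
  n <- length(x)
  times <- (seq_len(n) - 1) / fs - half
  nf <- stats::nextn(2 * n, 2)
  Xf <- stats::fft(c(x, rep(0, nf - n)))
  power <- matrix(0, nrow = n, ncol = length(freqs))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigma_t <- n_cycles / (2 * pi * f)
    half_w <- min(ceiling(4 * sigma_t * fs), floor((n - 1) / 2))
    tt <- (-half_w:half_w) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))  # unit energy
    Wf <- stats::fft(c(w, rep(0, nf - length(w))))
    conv <- stats::fft(Xf * Wf, inverse = TRUE)[seq_len(n + 2 * half_w)] / nf
    power[, j] <- Mod(conv[(half_w + 1):(half_w + n)])^2
  }
  keep <- times >= -half + trim - 1e-9 & times <= half - trim + 1e-9
  structure(list(times = times[keep], freqs = freqs,
                 power = power[keep, , drop = FALSE],
                 baseline_state = "raw"),
            class = "tfr_map")
}

#' Z-score baseline correction of a TFR map
#'
#' Per frequency, the mean and SD over the pre-event baseline window are
#' used to z-transform the whole epoch. An epoch with zero baseline SD at
#' any frequency is flagged `excluded` (power left untouched) rather than
#' propagating NaN.
#'
#' @param tfr a [morlet_tfr()] result
#' @param baseline baseline window in seconds, within the time grid
#' @return the map with `baseline_state = "zscored"`, or flagged excluded
#' @export
zscore_baseline <- function(tfr, baseline = c(-2.35, -1.5)) {
  stopifnot(inherits(tfr, "tfr_map"))
  rows <- tfr$times >= baseline[1] - 1e-9 & tfr$times <= baseline[2] + 1e-9
  if (!any(rows)) stop("baseline window outside the time grid")
  bl <- tfr$power[rows, , drop = FALSE]
  mu <- colMeans(bl)
  sdv <- apply(bl, 2, stats::sd)
  if (any(sdv <= 0)) {
    tfr$excluded <- TRUE
    return(tfr)
  }
  tfr$power <- sweep(sweep(tfr$power, 2, mu), 2, sdv, "/")
  tfr$baseline_state <- "zscored"
  tfr$excluded <- FALSE
  tfr
}

#' Average z-scored TFR maps across a subject's SO epochs
#'
#' @param tfrs list of z-scored [morlet_tfr()] maps; excluded maps are
#'   skipped
#' @return one `tfr_map` of the mean power, or NULL if none usable
#' @export
subject_mean_tfr <- function(tfrs) {
  usable <- Filter(function(m) isFALSE(m$excluded), tfrs)
  if (length(usable) == 0) return(NULL)
  out <- usable[[1]]
  out$power <- Reduce(`+`, lapply(usable, `[[`, "power")) / length(usable)
  out$n_epochs <- length(usable)
  out
}

# Large-but-finite stand-in for t at zero-variance pixels so TFCE stays
# finite; sign carries the direction of the constant difference.
T_CAP <- 1e6

#' Pixelwise paired t map between two conditions
#'
#' @param cond_a,cond_b lists of subject-mean `tfr_map`s, same subjects in
#'   the same order, identical grids
#' @return list with `t_map` (time x frequency), `diffs` (subject x pixel
#'   matrix of condition differences), `dims`, `times`, `freqs`, `n`
#' @export
paired_t_map <- function(cond_a, cond_b) {
  if (length(cond_a) != length(cond_b) || length(cond_a) < 2) {
    stop("need the same subjects (n >= 2) in both conditions")
  }
  dims <- dim(cond_a[[1]]$power)
  D <- t(vapply(seq_along(cond_a), function(i) {
    if (!identical(dim(cond_b[[i]]$power), dims)) {
      stop("TFR grids differ between conditions")
    }
    as.numeric(cond_a[[i]]$power - cond_b[[i]]$power)
  }, numeric(prod(dims))))
  t_vec <- t_from_diffs(D)
  list(t_map = matrix(t_vec, dims[1], dims[2]), diffs = D, dims = dims,
       times = cond_a[[1]]$times, freqs = cond_a[[1]]$freqs,
       n = length(cond_a))
}

# Paired t statistics from a subjects x pixels difference matrix, with
# optional sign flips. Zero-variance pixels map to 0 or +-T_CAP.
t_from_diffs <- function(D, signs = NULL) {
  n <- nrow(D)
  if (!is.null(signs)) {
    m <- as.numeric(crossprod(signs, D)) / n
  } else {
    m <- colMeans(D)
  }
  ss <- colSums(D^2)  # invariant under sign flips
  v <- pmax((ss - n * m^2) / (n - 1), 0)
  t <- ifelse(v > 0, m / sqrt(v / n),
              ifelse(abs(m) > 1e-12, sign(m) * T_CAP, 0))
  t
}

#' TFCE parameters
#'
#' @param E extent exponent
#' @param H height exponent
#' @param n_steps number of integration steps (dh = max|t| / n_steps)
#' @param n_perm number of sign-flip permutations
#' @param alpha familywise significance level
#' @return list of class `tfce_params`
#' @export
tfce_params <- function(E = 0.5, H = 2, n_steps = 100, n_perm = 1024,
                        alpha = 0.05) {
  stopifnot(E > 0, H > 0, n_steps >= 1, n_perm >= 100, alpha > 0, alpha < 1)
  structure(list(E = E, H = H, n_steps = n_steps, n_perm = n_perm,
                 alpha = alpha), class = "tfce_params")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates, over heights h from 0 to the pixel height in steps dh,
#' extent^E * h^H for the 4-connected suprathreshold cluster containing
#' the pixel. Positive and negative parts are enhanced separately, so the
#' transform is sign-symmetric: tfce(-m) = -tfce(m).
#'
#' @param m statistic matrix
#' @param E,H TFCE exponents
#' @param n_steps integration steps
#' @param dh step height; default `max(abs(m)) / n_steps`
#' @return TFCE-enhanced matrix
#' @export
tfce_transform <- function(m, E = 0.5, H = 2, n_steps = 100, dh = NULL) {
  m <- as.matrix(m)
  mx <- max(abs(m))
  if (mx == 0) return(m * 0)
  if (is.null(dh)) dh <- mx / n_steps
  nst <- max(1L, ceiling(mx / dh))
  pos <- tfce_nonneg(pmax(m, 0), dh, E, H, nst)
  neg <- tfce_nonneg(pmax(-m, 0), dh, E, H, nst)
  pos - neg
}

#' TFCE permutation test for a paired design
#'
#' Sign-flipping permutation test on per-subject condition difference
#' maps. The null distribution is the maximum |TFCE| over the map for
#' each sign-flip; the familywise-corrected p per pixel is
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`. When `2^n <= n_perm` all
#' sign patterns are enumerated instead and the p-value is exact.
#'
#' @param tmap result of [paired_t_map()]
#' @param params a [tfce_params()]
#' @param seed RNG seed for the permutation draws
#' @return list of class `tfce_result`: `t_map`, `tfce_map`, `p_map`,
#'   `null_max`, `significant_mask`, `exact`
#' @export
tfce_permutation <- function(tmap, params = tfce_params(), seed = 1L) {
  D <- tmap$diffs
  n <- nrow(D)
  dims <- tmap$dims
  dh <- max(abs(tmap$t_map)) / params$n_steps
  if (dh == 0) dh <- 1  # flat map; all TFCE zero
  obs <- tfce_transform(tmap$t_map, params$E, params$H, params$n_steps,
                        dh = dh)
  exact <- 2^n <= params$n_perm
  if (exact) {
    warning("2^n <= n_perm; enumerating all sign patterns (exact test)")
    signs_mat <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    signs_mat <- matrix(sample(c(-1, 1), n * params$n_perm, replace = TRUE),
                        nrow = params$n_perm, byrow = TRUE)
  }
  null_max <- apply(signs_mat, 1, function(s) {
    tp <- matrix(t_from_diffs(D, signs = s), dims[1], dims[2])
    tf <- tfce_transform(tp, params$E, params$H, params$n_steps, dh = dh)
    max(abs(tf))
  })
  a_obs <- abs(obs)
  exceed <- vapply(as.numeric(a_obs), function(v) sum(null_max >= v),
                   numeric(1))
  p <- if (exact) {
    matrix(exceed / length(null_max), dims[1], dims[2])
  } else {
    matrix((1 + exceed) / (length(null_max) + 1), dims[1], dims[2])
  }
  structure(list(t_map = tmap$t_map, tfce_map = obs, p_map = p,
                 null_max = null_max,
                 significant_mask = p < params$alpha,
                 exact = exact, times = tmap$times, freqs = tmap$freqs),
            class = "tfce_result")
}
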