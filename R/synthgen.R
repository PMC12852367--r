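#' Stimulation protocol description
#'
#' Describes the blocked slow-oscillatory stimulation protocol: a sinusoidal
#' current at `waveform_freq` oscillating between `current_min` and
#' `current_max`, delivered through a disc electrode of `electrode_diameter`
#' in repeated blocks of `block_duration` separated by at least `min_gap`.
#'
#' @param waveform_freq stimulation frequency in Hz
#' @param current_min,current_max current bounds in microamperes
#' @param block_duration duration of one stimulation block in seconds
#' @param min_gap minimum stimulation-free gap between blocks in seconds
#' @param n_blocks number of blocks per session (protocols use 7--15)
#' @param electrode_diameter stimulation electrode diameter in millimetres
#' @return an object of class `stim_protocol`
#' @export
stim_protocol <- function(waveform_freq = 0.75, current_min = 5,
                          current_max = 255, block_duration = 60,
                          min_gap = 90, n_blocks = 10,
                          electrode_diameter = 8) {
  stopifnot(current_max > current_min, current_min >= 0,
            block_duration > 0, min_gap > 0, electrode_diameter > 0,
            waveform_freq > 0, n_blocks >= 1)
  if (n_blocks < 7 || n_blocks > 15) {
    warning("n_blocks outside the standard 7-15 range")
  }
  structure(list(waveform_freq = waveform_freq, current_min = current_min,
                 current_max = current_max, block_duration = block_duration,
                 min_gap = min_gap, n_blocks = n_blocks,
                 electrode_diameter = electrode_diameter),
            class = "stim_protocol")
}

#' Peak current density of a disc electrode
#'
#' Converts the maximal stimulation current into a current density over the
#' electrode disc area, in mA/cm^2. With the default 255 uA through an 8-mm
#' electrode this is 0.507 mA/cm^2.
#'
#' @param protocol a [stim_protocol()]
#' @return peak current density in mA/cm^2
#' @export
peak_current_density <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  d_cm <- protocol$electrode_diameter / 10
  if (d_cm <= 0) stop("electrode diameter must be positive")
  area_cm2 <- pi * (d_cm / 2)^2
  (protocol$current_max / 1000) / area_cm2
}

#' Synthetic recording configuration
#'
#' Parameters of the synthetic polysomnography generator: an aperiodic
#' 1/f^x background, a train of isolated single-cycle slow oscillations
#' (SO), and spindle-band bursts whose envelope maximum is planted at an SO
#' phase drawn from a von Mises distribution.
#'
#' @param fs sampling rate in Hz (>= 100)
#' @param duration recording duration in seconds
#' @param aperiodic_exponent decay exponent x of the 1/f^x background
#' @param aperiodic_offset log10 power density at 1 Hz (log10 uV^2/Hz)
#' @param plateau_freq frequency (Hz) below which the background PSD
#'   flattens to a plateau (the low-frequency knee seen in neural spectra;
#'   the log-log PSD is exactly linear with slope -x above this point)
#' @param so_rate planted SO events per minute
#' @param so_amp_mean,so_amp_sd SO half-amplitude distribution in uV
#' @param so_freq_range SO cycle frequency range in Hz (cycle durations
#'   1/hi .. 1/lo seconds, which must lie within 0.8--2 s; the default
#'   stays clear of the duration-window edges so band-limiting, which
#'   broadens cycles slightly, cannot push planted events out of the
#'   detector's definition)
#' @param spindle_freq spindle carrier frequency in Hz
#' @param spindle_amp spindle burst peak amplitude in uV
#' @param spindle_burst_duration spindle burst duration in seconds
#'   (Gaussian envelope, SD = duration/6)
#' @param coupling_mean_phase mean SO phase of spindle maxima in degrees
#'   (0 = SO positive peak, 180 = trough)
#' @param coupling_kappa von Mises concentration of planted phases (>= 0)
#' @param coupling_probability probability that an SO carries a spindle
#' @param artifact_amp amplitude (uV) of the stimulation artifact added
#'   inside stimulation blocks; 0 leaves blocks clean
#' @param noise_seed integer seed making generation deterministic
#' @return an object of class `synth_config`
#' @export
synth_config <- function(fs = 200, duration = 600,
                         aperiodic_exponent = 2, aperiodic_offset = 1,
                         plateau_freq = 0.4,
                         so_rate = 18, so_amp_mean = 40, so_amp_sd = 8,
                         so_freq_range = c(0.6, 0.95),
                         spindle_freq = 13, spindle_amp = 15,
                         spindle_burst_duration = 0.75,
                         coupling_mean_phase = 333, coupling_kappa = 4,
                         coupling_probability = 0.5,
                         artifact_amp = 500, noise_seed = 1L) {
  if (!is.finite(aperiodic_exponent) || aperiodic_exponent < 0) {
    stop("aperiodic_exponent must be finite and >= 0")
  }
  stopifnot(fs >= 100, duration > 0, so_rate >= 0,
            coupling_kappa >= 0,
            coupling_probability >= 0, coupling_probability <= 1,
            length(so_freq_range) == 2L,
            so_freq_range[1] > 0, so_freq_range[2] < fs / 2,
            so_freq_range[1] <= so_freq_range[2],
            spindle_burst_duration > 0, spindle_amp >= 0)
  structure(list(fs = fs, duration = duration,
                 aperiodic_exponent = aperiodic_exponent,
                 aperiodic_offset = aperiodic_offset,
                 plateau_freq = plateau_freq,
                 so_rate = so_rate, so_amp_mean = so_amp_mean,
                 so_amp_sd = so_amp_sd, so_freq_range = so_freq_range,
                 spindle_freq = spindle_freq, spindle_amp = spindle_amp,
                 spindle_burst_duration = spindle_burst_duration,
                 coupling_mean_phase = wrap_deg(coupling_mean_phase),
                 coupling_kappa = coupling_kappa,
                 coupling_probability = coupling_probability,
                 artifact_amp = artifact_amp,
                 noise_seed = as.integer(noise_seed)),
            class = "synth_config")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to the uniform
#' distribution on the circle.
#'
#' @param n number of draws
#' @param mu mean direction in radians
#' @param kappa concentration parameter (>= 0)
#' @return angles in radians in `[0, 2*pi)`
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

#' Aperiodic 1/f^x background signal
#'
#' Spectrally shaped Gaussian noise whose expected one-sided power spectral
#' density is `10^offset * f^(-x)` (uV^2/Hz), i.e. log-log linear with
#' slope `-x` over the fit range. `x = 0` gives white noise.
#'
#' @param config a [synth_config()]
#' @param seed seed used for this component (default the config seed)
#' @return numeric signal of length `fs * duration`, zero mean
#' @export
make_aperiodic_background <- function(config, seed = config$noise_seed) {
  stopifnot(inherits(config, "synth_config"))
  x <- config$aperiodic_exponent
  if (!is.finite(x)) stop("aperiodic exponent must be finite")
  fs <- config$fs
  n <- round(fs * config$duration)
  set.seed(seed)
  freqs <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  nyq_i <- floor(n / 2) + 1L
  f_pos <- freqs[2:nyq_i]
  # FFT coefficient scale giving one-sided PSD 10^offset * f^-x above the
  # low-frequency plateau (knee), constant below it
  f_shaped <- pmax(f_pos, config$plateau_freq)
  s_pos <- sqrt(10^config$aperiodic_offset * f_shaped^(-x) * fs * n / 2)
  z <- complex(real = stats::rnorm(nyq_i - 1L, sd = sqrt(0.5)),
               imaginary = stats::rnorm(nyq_i - 1L, sd = sqrt(0.5)))
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2:nyq_i] <- s_pos * z
  if (n %% 2L == 0L) spec[nyq_i] <- complex(real = Re(spec[nyq_i]) * sqrt(2))
  # Hermitian symmetry for a real signal
  spec[n:(nyq_i + ifelse(n %% 2L == 0L, 1L, 0L))] <-
    Conj(spec[2:(n - nyq_i + ifelse(n %% 2L == 0L, 0L, 1L) + 1L)])
  sig <- Re(stats::fft(spec, inverse = TRUE)) / n
  sig - mean(sig)
}

# Ground-truth container for planted events.
new_ground_truth <- function(protocol = NULL, true_exponent = NA_real_) {
  structure(list(so_trough_times = numeric(0), so_amplitudes = numeric(0),
                 so_onsets = numeric(0), so_durations = numeric(0),
                 spindle_phases = numeric(0), spindle_times = numeric(0),
                 coupled_events = integer(0),
                 true_exponent = true_exponent, protocol = protocol),
            class = "ground_truth")
}

#' Train of isolated single-cycle slow oscillations
#'
#' Plants `so_rate` events/min of one full SO cycle each: a negative
#' half-wave followed by a positive half-wave, `-A * sin(2*pi*t/T)` over a
#' cycle of duration `T` drawn from `1/so_freq_range`, flanked by a small
#' positive lead-in bump and a shallow negative rebound (20% of the cycle
#' amplitude, 0.35 s half-sines). The flanks give the template the
#' K-complex-like morphology of real slow oscillations and pin the
#' cycle-delimiting zero-crossings to the event itself rather than to
#' whatever the background happens to do at the cycle edges. Events are
#' placed at Poisson-thinned, non-overlapping times restricted to
#' `within` spans.
#'
#' @param config a [synth_config()]
#' @param seed component seed
#' @param within optional two-column matrix of (start, stop) spans in
#'   seconds restricting where events may be planted
#' @return list with `signal` (uV) and `truth` (a `ground_truth`)
#' @export
make_so_train <- function(config, seed = config$noise_seed + 1L,
                          within = NULL) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(fs * config$duration)
  sig <- numeric(n)
  truth <- new_ground_truth()
  if (config$so_rate == 0) return(list(signal = sig, truth = truth))
  t_max <- max(1 / config$so_freq_range[1], 0.8)
  if (t_max > 2) stop("so_freq_range implies cycle durations above 2 s")
  if (is.null(within)) within <- matrix(c(0, config$duration), ncol = 2)
  avail <- sum(within[, 2] - within[, 1])
  # isolation gap: band-limiting smears each cycle, so "isolated" means
  # separated by more than the filter spread (flanks included)
  gap <- 1.2
  if (config$so_rate / 60 * (t_max + gap) > 0.9) {
    stop("so_rate too high for non-overlapping events")
  }
  set.seed(seed)
  n_ev <- stats::rpois(1, config$so_rate * avail / 60)
  if (n_ev == 0) return(list(signal = sig, truth = truth))
  # draw within the allowed spans, then thin overlaps
  u <- stats::runif(n_ev, 0, avail)
  edges <- cumsum(c(0, within[, 2] - within[, 1]))
  span_i <- findInterval(u, edges, rightmost.closed = TRUE)
  t0 <- sort(within[span_i, 1] + (u - edges[span_i]))
  f_cyc <- stats::runif(length(t0), config$so_freq_range[1],
                        config$so_freq_range[2])
  dur <- 1 / f_cyc
  # floor keeps every planted event above the detectability range the
  # recovery contract assumes (p2p >= 40 uV against the default background)
  amp <- pmax(stats::rnorm(length(t0), config$so_amp_mean,
                           config$so_amp_sd), 20)
  # thin: enforce a silent gap between cycles, keep cycles inside one span
  inside <- vapply(seq_along(t0), function(i) {
    any(t0[i] >= within[, 1] & t0[i] + dur[i] <= within[, 2])
  }, logical(1))
  keep <- logical(length(t0))
  last_end <- -Inf
  for (i in seq_along(t0)) {
    if (inside[i] && t0[i] >= last_end + gap &&
        t0[i] + dur[i] <= config$duration) {
      keep[i] <- TRUE
      last_end <- t0[i] + dur[i]
    }
  }
  t0 <- t0[keep]; dur <- dur[keep]; amp <- amp[keep]
  tb <- 0.35   # flank duration (s)
  b <- 0.3     # flank amplitude fraction
  for (i in seq_along(t0)) {
    tt <- seq(-tb, dur[i] + tb, by = 1 / fs)
    seg <- ifelse(tt < 0, b * amp[i] * sin(pi * (tt + tb) / tb),
           ifelse(tt <= dur[i], -amp[i] * sin(2 * pi * tt / dur[i]),
                  -b * amp[i] * sin(pi * (tt - dur[i]) / tb)))
    j <- round((t0[i] + tt) * fs) + 1L
    ok <- j >= 1L & j <= n
    sig[j[ok]] <- sig[j[ok]] + seg[ok]
  }
  truth$so_trough_times <- t0 + dur / 4
  truth$so_amplitudes <- amp
  truth$so_onsets <- t0
  truth$so_durations <- dur
  list(signal = sig, truth = truth)
}

#' Spindle bursts coupled to planted slow oscillations
#'
#' For each planted SO event (with probability `coupling_probability`) adds
#' a Gaussian-envelope burst at `spindle_freq` whose envelope maximum falls
#' at the time where the SO cycle attains a phase drawn from
#' `vonMises(coupling_mean_phase, coupling_kappa)`. Phase convention:
#' 0 deg = SO positive peak, 90 = mid falling flank, 180 = trough,
#' 270 = mid rising flank.
#'
#' @param so_truth ground truth from [make_so_train()]
#' @param config a [synth_config()]
#' @param seed component seed
#' @return list with `signal` (uV) and the updated `truth`
#' @export
make_coupled_spindles <- function(so_truth, config,
                                  seed = config$noise_seed + 2L) {
  stopifnot(inherits(so_truth, "ground_truth"),
            inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(fs * config$duration)
  sig <- numeric(n)
  truth <- so_truth
  n_so <- length(truth$so_onsets)
  if (n_so == 0 || config$coupling_probability == 0 ||
      config$spindle_amp == 0) {
    return(list(signal = sig, truth = truth))
  }
  set.seed(seed)
  coupled <- which(stats::runif(n_so) < config$coupling_probability)
  if (length(coupled) == 0) return(list(signal = sig, truth = truth))
  phi <- rvonmises(length(coupled), deg2rad(config$coupling_mean_phase),
                   config$coupling_kappa)
  bd <- config$spindle_burst_duration
  sd_env <- bd / 6
  for (k in seq_along(coupled)) {
    i <- coupled[k]
    t0 <- truth$so_onsets[i]; dur <- truth$so_durations[i]
    if (bd > dur) {
      warning("spindle burst longer than SO cycle; envelope truncated")
    }
    # SO waveform -sin maps phase 180 deg -> t0 + T/4, 0 deg -> t0 + 3T/4
    frac <- ((phi[k] - pi / 2) %% (2 * pi)) / (2 * pi)
    tc <- t0 + frac * dur
    half <- min(bd, dur) / 2
    tt <- seq(-half, half, by = 1 / fs)
    burst <- config$spindle_amp * exp(-tt^2 / (2 * sd_env^2)) *
      cos(2 * pi * config$spindle_freq * tt)
    j <- round((tc + tt) * fs) + 1L
    ok <- j >= 1L & j <= n
    sig[j[ok]] <- sig[j[ok]] + burst[ok]
    truth$spindle_phases <- c(truth$spindle_phases, wrap_deg(rad2deg(phi[k])))
    truth$spindle_times <- c(truth$spindle_times, tc)
    truth$coupled_events <- c(truth$coupled_events, i)
  }
  list(signal = sig, truth = truth)
}

# Block schedule: onsets/offsets satisfying block_duration and >= min_gap,
# with mild uniform jitter of the gaps where the duration allows it.
schedule_blocks <- function(config, protocol, lead_in = 90) {
  nb <- protocol$n_blocks
  need <- nb * (protocol$block_duration + protocol$min_gap)
  if (config$duration < need) {
    stop("recording too short for the requested block schedule")
  }
  slack <- config$duration - lead_in - nb * protocol$block_duration -
    (nb - 1) * protocol$min_gap - protocol$block_duration
  if (slack < 0) {
    lead_in <- max(60, lead_in + slack)
    slack <- 0
  }
  extra <- if (nb > 1 && slack > 0) {
    e <- stats::runif(nb - 1, 0, min(30, slack / (nb - 1)))
    e
  } else numeric(max(nb - 1, 0))
  onsets <- lead_in + (seq_len(nb) - 1) * protocol$block_duration +
    cumsum(c(0, protocol$min_gap + extra))
  data.frame(onset = onsets, offset = onsets + protocol$block_duration)
}

#' Generate one synthetic recording
#'
#' Sums the aperiodic background, the SO train, and coupled spindle bursts;
#' annotates a blocked stimulation protocol (STIM_BLOCK intervals, 1-min
#' POST_WINDOW intervals after each block, N2 stage labels over the block
#' region and wake elsewhere) and optionally contaminates stimulation
#' blocks with a large-amplitude artifact. SO events are planted only
#' outside stimulation blocks so that post-block analysis windows carry
#' clean events.
#'
#' @param config a [synth_config()]
#' @param protocol a [stim_protocol()]
#' @param subject,condition metadata stored on the recording
#' @return list with `recording` (a [recording()]) and `truth`
#' @export
generate_recording <- function(config, protocol = stim_protocol(),
                               subject = "s01", condition = "sham") {
  stopifnot(inherits(config, "synth_config"),
            inherits(protocol, "stim_protocol"))
  fs <- config$fs
  n <- round(fs * config$duration)
  set.seed(config$noise_seed)
  blocks <- schedule_blocks(config, protocol)
  # events are planted in the stimulation-free spans around the blocks
  free <- cbind(c(0, blocks$offset), c(blocks$onset, config$duration))
  free <- free[free[, 2] - free[, 1] > 2.5, , drop = FALSE]
  so <- make_so_train(config, seed = config$noise_seed + 1L, within = free)
  sp <- make_coupled_spindles(so$truth, config,
                              seed = config$noise_seed + 2L)
  truth <- sp$truth
  truth$true_exponent <- config$aperiodic_exponent
  truth$protocol <- protocol
  base_fz <- make_aperiodic_background(config, seed = config$noise_seed + 3L)
  composite <- so$signal + sp$signal
  t_grid <- (seq_len(n) - 1L) / fs
  artifact <- numeric(n)
  if (config$artifact_amp > 0) {
    for (b in seq_len(nrow(blocks))) {
      idx <- which(t_grid >= blocks$onset[b] & t_grid < blocks$offset[b])
      artifact[idx] <- config$artifact_amp *
        sin(2 * pi * protocol$waveform_freq * t_grid[idx])
    }
  }
  chans <- c("Fz", "FC1", "FC2")
  sig <- matrix(0, nrow = length(chans), ncol = n,
                dimnames = list(chans, NULL))
  sig["Fz", ] <- base_fz + composite + artifact
  for (k in 2:3) {
    bg <- make_aperiodic_background(config,
                                    seed = config$noise_seed + 3L + k)
    sig[chans[k], ] <- bg + 0.8 * composite + artifact
  }
  ann <- data.frame(
    onset = blocks$onset, duration = blocks$offset - blocks$onset,
    label = "STIM_BLOCK", stringsAsFactors = FALSE)
  post <- data.frame(
    onset = blocks$offset,
    duration = pmin(60, c(blocks$onset[-1], config$duration) -
                      blocks$offset),
    label = "POST_WINDOW", stringsAsFactors = FALSE)
  region_start <- max(0, blocks$onset[1] - 90)
  region_stop <- min(config$duration, blocks$offset[nrow(blocks)] + 90)
  stages <- data.frame(
    onset = c(0, region_start, region_stop),
    duration = c(region_start, region_stop - region_start,
                 config$duration - region_stop),
    label = c("STAGE_W", "STAGE_N2", "STAGE_W"), stringsAsFactors = FALSE)
  stages <- stages[stages$duration > 0, ]
  rec <- recording(sig, fs, annotations = rbind(ann, post, stages),
                   subject = subject, condition = condition)
  list(recording = rec, truth = truth)
}

known_effect_keys <- c("phase_shift", "exponent_shift",
                       "spindle_amp_shift", "meq_spindle_slope")

#' Plan a synthetic cohort
#'
#' Builds the per-subject x condition generating parameters for a
#' three-condition within-subject design (sham, anodal, cathodal) with
#' plantable condition effects and an MEQ-moderated spindle effect, plus
#' deterministic per-cell seeds. Cells are realized lazily with
#' [realize_cohort_cell()] so that large cohorts never have to be held in
#' memory at once; [generate_cohort()] materializes them.
#'
#' Recognized `effects` entries (each a numeric vector named by condition;
#' missing conditions default to 0):
#' \describe{
#'   \item{phase_shift}{added to `coupling_mean_phase`, degrees}
#'   \item{exponent_shift}{added to `aperiodic_exponent`}
#'   \item{spindle_amp_shift}{added to `spindle_amp`, uV}
#'   \item{meq_spindle_slope}{uV of spindle amplitude per MEQ point
#'     (MEQ centered at 60), i.e. the planted moderation}
#' }
#'
#' @param n_subjects number of subjects (>= 2)
#' @param effects named list of planted effects (see Details)
#' @param master_seed integer master seed
#' @param config baseline [synth_config()] shared by all cells
#' @param protocol a [stim_protocol()]
#' @param conditions condition labels
#' @param meq_mean,meq_sd parameters of the discretized-normal MEQ
#'   distribution, clipped to 16--86 (aged samples skew toward morningness)
#' @return a `cohort_plan`: subject table, per-cell configs and manifest
#' @export
cohort_plan <- function(n_subjects = 22, effects = list(),
                        master_seed = 1L, config = synth_config(),
                        protocol = stim_protocol(),
                        conditions = c("sham", "anodal", "cathodal"),
                        meq_mean = 60, meq_sd = 7) {
  stopifnot(n_subjects >= 2)
  bad <- setdiff(names(effects), known_effect_keys)
  if (length(bad)) stop("unknown effect key(s): ", paste(bad, collapse = ", "))
  eff <- lapply(known_effect_keys, function(k) {
    v <- stats::setNames(rep(0, length(conditions)), conditions)
    if (!is.null(effects[[k]])) {
      stopifnot(all(names(effects[[k]]) %in% conditions))
      v[names(effects[[k]])] <- effects[[k]]
    }
    v
  })
  names(eff) <- known_effect_keys
  set.seed(master_seed)
  meq <- pmin(pmax(round(stats::rnorm(n_subjects, meq_mean, meq_sd)), 16), 86)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      n_subjects * length(conditions))
  subjects <- data.frame(
    subject = sprintf("s%02d", seq_len(n_subjects)),
    meq = meq,
    chronotype = vapply(meq, meq_classify, character(1)),
    stringsAsFactors = FALSE)
  cells <- expand.grid(subject = subjects$subject, condition = conditions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$seed <- seeds[seq_len(nrow(cells))]
  structure(list(subjects = subjects, cells = cells, effects = eff,
                 base_config = config, protocol = protocol,
                 conditions = conditions, meq_center = meq_mean,
                 master_seed = master_seed,
                 manifest = list(n_subjects = n_subjects,
                                 conditions = conditions,
                                 master_seed = master_seed,
                                 effects = eff,
                                 base_config = unclass(config))),
            class = "cohort_plan")
}

# Generating config for one subject x condition cell, with effects applied.
cell_config <- function(plan, subject, condition) {
  row <- plan$cells[plan$cells$subject == subject &
                      plan$cells$condition == condition, ]
  if (nrow(row) != 1L) stop("unknown cohort cell")
  meq <- plan$subjects$meq[plan$subjects$subject == subject]
  cfg <- plan$base_config
  eff <- plan$effects
  cfg$coupling_mean_phase <-
    wrap_deg(cfg$coupling_mean_phase + eff$phase_shift[[condition]])
  cfg$aperiodic_exponent <-
    cfg$aperiodic_exponent + eff$exponent_shift[[condition]]
  cfg$spindle_amp <- max(0, cfg$spindle_amp +
                           eff$spindle_amp_shift[[condition]] +
                           eff$meq_spindle_slope[[condition]] *
                           (meq - plan$meq_center))
  cfg$noise_seed <- row$seed
  cfg
}

#' Realize one cohort cell
#'
#' @param plan a [cohort_plan()]
#' @param subject,condition cell identifiers
#' @return list with `recording` and `truth` for that cell
#' @export
realize_cohort_cell <- function(plan, subject, condition) {
  stopifnot(inherits(plan, "cohort_plan"))
  cfg <- cell_config(plan, subject, condition)
  generate_recording(cfg, plan$protocol, subject = subject,
                     condition = condition)
}

#' Generate a full synthetic cohort
#'
#' Materializes every subject x condition recording of a [cohort_plan()].
#' For large cohorts prefer iterating over [realize_cohort_cell()].
#'
#' @inheritParams cohort_plan
#' @return list with `subjects`, `recordings` (nested
#'   `[[subject]][[condition]]` lists of recording + truth), `manifest`
#'   and the `plan`
#' @export
generate_cohort <- function(n_subjects = 22, effects = list(),
                            master_seed = 1L, config = synth_config(),
                            protocol = stim_protocol(),
                            conditions = c("sham", "anodal", "cathodal")) {
  plan <- cohort_plan(n_subjects, effects, master_seed, config, protocol,
                      conditions)
  recs <- lapply(plan$subjects$subject, function(s) {
    out <- lapply(conditions, function(cnd) realize_cohort_cell(plan, s, cnd))
    names(out) <- conditions
    out
  })
  names(recs) <- plan$subjects$subject
  list(subjects = plan$subjects, recordings = recs,
       manifest = plan$manifest, plan = plan)
}
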