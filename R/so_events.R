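#' SO detection parameters
#'
#' @param filter_band band-pass range in Hz for the SO filter
#' @param percentile individualized amplitude percentile (events whose
#'   trough-to-peak amplitude reaches this percentile of all candidate
#'   cycles in the session are kept)
#' @param dur_min,dur_max admissible cycle duration in seconds, measured
#'   between two consecutive positive-to-negative zero-crossings
#' @return a list of class `so_params`
#' @export
so_params <- function(filter_band = c(0.16, 1.25), percentile = 65,
                      dur_min = 0.8, dur_max = 2.0) {
  stopifnot(filter_band[1] > 0, filter_band[1] < filter_band[2],
            dur_min > 0, dur_min < dur_max,
            percentile >= 0, percentile <= 100)
  structure(list(filter_band = filter_band, percentile = percentile,
                 dur_min = dur_min, dur_max = dur_max),
            class = "so_params")
}

#' Zero-phase FIR band-pass for the SO band
#'
#' Windowed-sinc (Hamming) FIR with a 0.1 Hz transition at the low edge
#' and 0.5 Hz at the high edge, applied with delay compensation so the
#' output is exactly zero-phase.
#'
#' @param signal numeric signal
#' @param fs sampling rate in Hz
#' @param band length-2 band in Hz
#' @return filtered signal, same length
#' @export
bandpass_so <- function(signal, fs, band = c(0.16, 1.25)) {
  stopifnot(fs > 2 * band[2])
  h <- fir_bandpass(band[1], band[2], fs, trans_lo = 0.1, trans_hi = 0.5)
  if (length(signal) < length(h) / 4) {
    stop("signal shorter than the SO filter supports")
  }
  filt_zero_phase(as.numeric(signal), h)
}

#' Find candidate SO cycles by zero-crossings
#'
#' Identifies all positive-to-negative zero-crossings in the SO-filtered
#' signal; every pair of consecutive pos-to-neg crossings whose spacing
#' lies within `[dur_min, dur_max]` delimits one candidate cycle (negative
#' half-wave first, then positive). The trough is the most negative sample
#' before the interior negative-to-positive crossing and the peak the most
#' positive sample after it. Candidates touching the signal edges are
#' dropped.
#'
#' @param filtered SO-band filtered signal
#' @param fs sampling rate in Hz
#' @param params a [so_params()]
#' @param t_offset seconds added to all reported times (segment start time)
#' @return data frame of candidate events (possibly empty) with columns
#'   t_pn1, t_np, t_pn2, trough_time, trough_amp, peak_time, peak_amp,
#'   p2p_amp, neg_halfwave_dur, pos_halfwave_dur, slope
#' @export
find_candidates <- function(filtered, fs, params = so_params(),
                            t_offset = 0) {
  x <- as.numeric(filtered)
  n <- length(x)
  empty <- data.frame(t_pn1 = numeric(0), t_np = numeric(0),
                      t_pn2 = numeric(0), trough_time = numeric(0),
                      trough_amp = numeric(0), peak_time = numeric(0),
                      peak_amp = numeric(0), p2p_amp = numeric(0),
                      neg_halfwave_dur = numeric(0),
                      pos_halfwave_dur = numeric(0), slope = numeric(0))
  if (n < 3) return(empty)
  s <- sign(x)
  s[s == 0] <- 1
  d <- diff(s)
  pn <- which(d < 0)  # last sample index before a pos-to-neg crossing
  if (length(pn) < 2) return(empty)
  # linear interpolation of the crossing time between samples i and i+1
  cross_t <- function(i) (i - 1 + x[i] / (x[i] - x[i + 1])) / fs
  rows <- list()
  for (k in seq_len(length(pn) - 1L)) {
    i1 <- pn[k]; i2 <- pn[k + 1L]
    dur <- cross_t(i2) - cross_t(i1)
    if (dur < params$dur_min || dur > params$dur_max) next
    seg <- x[(i1 + 1L):i2]
    # trough = most negative point of the cycle; the neg-to-pos crossing
    # that follows it separates the half-waves (robust to small wiggles
    # riding on the half-wave tails)
    tr_i <- i1 + which.min(seg)
    np_rel <- which(diff(sign(ifelse(seg == 0, 1, seg))) > 0)
    np_rel <- np_rel[i1 + np_rel >= tr_i]
    if (length(np_rel) == 0) next
    i_np <- i1 + np_rel[1]
    if (i_np >= i2) next
    pk_i <- i_np + which.max(x[(i_np + 1L):i2])
    t_pn1 <- cross_t(i1); t_np <- cross_t(i_np); t_pn2 <- cross_t(i2)
    trough_amp <- x[tr_i]; peak_amp <- x[pk_i]
    if (trough_amp >= 0 || peak_amp <= 0) next
    trough_time <- (tr_i - 1) / fs
    peak_time <- (pk_i - 1) / fs
    rows[[length(rows) + 1L]] <- data.frame(
      t_pn1 = t_pn1, t_np = t_np, t_pn2 = t_pn2,
      trough_time = trough_time, trough_amp = trough_amp,
      peak_time = peak_time, peak_amp = peak_amp,
      p2p_amp = peak_amp - trough_amp,
      neg_halfwave_dur = t_np - t_pn1,
      pos_halfwave_dur = t_pn2 - t_np,
      slope = (peak_amp - trough_amp) / (peak_time - trough_time))
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[, c("t_pn1", "t_np", "t_pn2", "trough_time", "peak_time")] <-
    out[, c("t_pn1", "t_np", "t_pn2", "trough_time", "peak_time")] + t_offset
  out
}

#' Apply the individualized percentile amplitude threshold
#'
#' Keeps candidates whose trough-to-peak amplitude is at or above the
#' session's `percentile` (type-7 linear interpolation) of all candidate
#' amplitudes. The threshold is computed within the candidate set passed
#' in (one subject-session), so concatenating sessions is not equivalent
#' to detecting per session.
#'
#' @param candidates data frame from [find_candidates()]
#' @param params a [so_params()]
#' @return the retained events with an attached `threshold` attribute
#' @export
detect_so_events <- function(candidates, params = so_params()) {
  if (nrow(candidates) == 0) {
    attr(candidates, "threshold") <- NA_real_
    return(candidates)
  }
  if (nrow(candidates) < 3) {
    warning("fewer than 3 candidates; amplitude threshold undefined, ",
            "all candidates retained")
    attr(candidates, "threshold") <- NA_real_
    return(candidates)
  }
  thr <- stats::quantile(candidates$p2p_amp, params$percentile / 100,
                         type = 7, names = FALSE)
  out <- candidates[candidates$p2p_amp >= thr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Summarize SO event morphology
#'
#' Per-event means of the Fig-style morphology outcomes: count, down-state
#' magnitude (|trough amplitude|), up-state amplitude, peak-to-peak
#' amplitude, trough-to-peak slope, and negative/positive half-wave
#' durations.
#'
#' @param events data frame of detected events
#' @return one-row data frame of summary statistics
#' @export
summarize_morphology <- function(events) {
  if (nrow(events) == 0) {
    return(data.frame(count = 0L, downstate_mag = NA_real_,
                      upstate_amp = NA_real_, p2p_amp = NA_real_,
                      slope = NA_real_, neg_halfwave_dur = NA_real_,
                      pos_halfwave_dur = NA_real_))
  }
  data.frame(count = nrow(events),
             downstate_mag = mean(abs(events$trough_amp)),
             upstate_amp = mean(events$peak_amp),
             p2p_amp = mean(events$p2p_amp),
             slope = mean(events$slope),
             neg_halfwave_dur = mean(events$neg_halfwave_dur),
             pos_halfwave_dur = mean(events$pos_halfwave_dur))
}

#' Cut trough-centered event epochs
#'
#' 5-s epochs centered on each event trough (t = 0 at the trough). Events
#' whose window exceeds the recording bounds, or overlaps any span in
#' `avoid`, are dropped.
#'
#' @param signal the (unfiltered) analysis-channel signal
#' @param events detected events (needs `trough_time`)
#' @param fs sampling rate in Hz
#' @param half_width epoch half width in seconds
#' @param avoid optional two-column matrix of (start, stop) spans to avoid
#'   (e.g. stimulation blocks)
#' @return list of numeric epochs, each with attributes `t0` (epoch start
#'   time in the recording) and `fs`
#' @export
extract_event_epochs <- function(signal, events, fs, half_width = 2.5,
                                 avoid = NULL) {
  n <- length(signal)
  out <- list()
  nsamp <- round(2 * half_width * fs) + 1L
  for (k in seq_len(nrow(events))) {
    tc <- events$trough_time[k]
    i0 <- round((tc - half_width) * fs) + 1L
    i1 <- i0 + nsamp - 1L
    if (i0 < 1L || i1 > n) next
    if (!is.null(avoid) && nrow(avoid) &&
        any(tc - half_width < avoid[, 2] & tc + half_width > avoid[, 1])) {
      next
    }
    ep <- signal[i0:i1]
    attr(ep, "t0") <- (i0 - 1L) / fs
    attr(ep, "fs") <- fs
    out[[length(out) + 1L]] <- ep
  }
  out
}

#' Detect SO events on the post-block intervals of a recording
#'
#' Convenience wrapper running the full detector on one recording: selects
#' the analysis channel, band-pass filters the whole signal, finds
#' candidates within each unclipped post-block interval, pools them, and
#' applies the session-level percentile threshold.
#'
#' @param rec a [recording()]
#' @param params a [so_params()]
#' @param intervals optional precomputed [extract_intervals()] table
#' @param kinds interval kinds to scan for events
#' @return list with `events`, `candidates`, `channel`, `threshold`
#' @export
detect_so_in_recording <- function(rec, params = so_params(),
                                   intervals = NULL,
                                   kinds = "post_block") {
  ch <- select_channel(rec)
  if (is.null(intervals)) intervals <- extract_intervals(rec)
  ivs <- intervals[intervals$kind %in% kinds, , drop = FALSE]
  filt <- bandpass_so(ch$signal, rec$fs, params$filter_band)
  cands <- do.call(rbind, lapply(seq_len(nrow(ivs)), function(i) {
    seg <- cut_segment(filt, rec$fs, ivs$start[i], ivs$stop[i])
    find_candidates(seg, rec$fs, params, t_offset = ivs$start[i])
  }))
  if (is.null(cands)) cands <- find_candidates(numeric(0), rec$fs, params)
  ev <- detect_so_events(cands, params)
  list(events = ev, candidates = cands, channel = ch$channel,
       threshold = attr(ev, "threshold"))
}
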