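# Shared fixtures for detector-recovery and coupling tests.

# Match detected events against planted trough times. Recall counts planted
# troughs with a detection within `radius`; precision counts detections
# near a planted trough; terr is the mean |error| over the matches.
match_planted <- function(events, trough_times, radius = 0.25) {
  e <- vapply(trough_times,
              function(t) min(abs(events$trough_time - t)), numeric(1))
  hit <- e <= radius
  prec <- mean(vapply(events$trough_time,
                      function(t) any(abs(trough_times - t) <= radius),
                      logical(1)))
  list(recall = mean(hit), precision = prec,
       terr = mean(e[hit]), n = length(trough_times))
}

# Planted events fully contained in one of the (start, stop) spans; only
# these are visible to a detector restricted to those spans.
contained_truth <- function(truth, spans) {
  keep <- vapply(seq_along(truth$so_onsets), function(i) {
    any(truth$so_onsets[i] >= spans[, 1] &
          truth$so_onsets[i] + truth$so_durations[i] <= spans[, 2])
  }, logical(1))
  truth$so_trough_times[keep]
}

# A 5-s trough-centered epoch: 0.75 Hz SO (trough at t = 0) plus a 13 Hz
# Gaussian burst whose envelope peaks at the requested SO phase.
coupling_epoch <- function(phase_deg, fs = 200, f_so = 0.75, so_amp = 40,
                           sp_amp = 15, noise_sd = 0) {
  tt <- seq(-2.5, 2.5, by = 1 / fs)
  so <- -so_amp * cos(2 * pi * f_so * tt)
  tc <- (phase_deg - 180) / 360 / f_so
  burst <- sp_amp * exp(-(tt - tc)^2 / (2 * (0.75 / 6)^2)) *
    cos(2 * pi * 13 * (tt - tc))
  x <- so + burst
  if (noise_sd > 0) x <- x + stats::rnorm(length(tt), sd = noise_sd)
  x
}

# Long table for a 3-condition within-subject design.
long_table <- function(Y, conditions = colnames(Y)) {
  data.frame(subject = rep(rownames(Y), ncol(Y)),
             condition = rep(conditions, each = nrow(Y)),
             value = as.numeric(Y), stringsAsFactors = FALSE)
}

# 6-subject fixture used by the closed-form oracle tests.
oracle_Y <- function() {
  matrix(c(12.1, 10.3, 14.2,
           11.0,  9.8, 12.9,
           13.5, 12.0, 15.1,
            9.7,  9.9, 11.4,
           12.8, 11.1, 13.0,
           10.9, 10.2, 12.2), nrow = 6, byrow = TRUE,
         dimnames = list(sprintf("s%d", 1:6),
                         c("sham", "anodal", "cathodal")))
}
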