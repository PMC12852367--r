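test_that("the SO band-pass has the stated frequency response", {
  fs <- 200
  tt <- (0:(fs * 120 - 1)) / fs
  mid <- 4000:20000
  x75 <- sin(2 * pi * 0.75 * tt)
  expect_equal(sd(bandpass_so(x75, fs)[mid]) / sd(x75[mid]), 1,
               tolerance = 0.05)
  x13 <- sin(2 * pi * 13 * tt)
  expect_lt(sd(bandpass_so(x13, fs)[mid]) / sd(x13[mid]), 0.05)
  dc <- bandpass_so(x75 + 100, fs)
  expect_lt(abs(mean(dc[mid])), 1)
  expect_error(bandpass_so(numeric(10), fs), "shorter")
})

test_that("zero-crossing candidates follow the duration rule", {
  fs <- 200
  expect_equal(nrow(find_candidates(numeric(fs * 30), fs)), 0)
  tt <- (0:(fs * 60 - 1)) / fs
  c75 <- find_candidates(sin(2 * pi * 0.75 * tt), fs)
  expect_equal(nrow(c75), 44)
  expect_equal(unique(round(c75$t_pn2 - c75$t_pn1, 3)), 1.333)
  # 0.4 Hz cycles last 2.5 s: rejected
  expect_equal(nrow(find_candidates(sin(2 * pi * 0.4 * tt), fs)), 0)
})

test_that("the percentile threshold keeps the top 35% with >= ties", {
  fs <- 200
  # 101 planted cycles; the last has no closing crossing, leaving 100
  # candidates with distinct amplitudes
  amps <- seq(10, 110)
  sig <- unlist(lapply(amps, function(a) {
    tcyc <- seq(0, 1.25, by = 1 / fs)[-1]
    c(-a * sin(2 * pi * tcyc / 1.25), numeric(fs * 0.3))
  }))
  cands <- find_candidates(c(numeric(fs), sig, numeric(fs)), fs)
  expect_equal(nrow(cands), 100)
  kept <- detect_so_events(cands)
  expect_equal(nrow(kept), 35)
  expect_true(all(kept$p2p_amp >= attr(kept, "threshold")))
  # all-equal amplitudes: everything is at the threshold, all retained
  tied <- cands
  tied$p2p_amp <- 50
  expect_equal(nrow(detect_so_events(tied)), 100)
  expect_warning(detect_so_events(cands[1:2, ]), "fewer than 3")
})

test_that("morphology summaries follow the event geometry", {
  expect_equal(summarize_morphology(
    find_candidates(numeric(100), 200))$count, 0)
  fs <- 200
  # asymmetric cycle: negative half 1.0 s, positive half 0.5 s; a small
  # trailing dip provides the closing positive-to-negative crossing
  t1 <- seq(0, 1, by = 1 / fs)[-1]
  t2 <- seq(0, 0.5, by = 1 / fs)[-1]
  t3 <- seq(0, 0.3, by = 1 / fs)[-1]
  cyc <- c(numeric(fs * 2), -50 * sin(pi * t1), 50 * sin(pi * t2 / 0.5),
           -0.5 * sin(pi * t3 / 0.3), numeric(fs * 2))
  cands <- find_candidates(cyc, fs)
  expect_equal(nrow(cands), 1)
  s <- summarize_morphology(cands)
  expect_equal(s$neg_halfwave_dur, 1.0, tolerance = 0.02)
  expect_equal(s$pos_halfwave_dur, 0.5, tolerance = 0.02)
  expect_equal(s$downstate_mag, 50, tolerance = 0.5)
  expect_equal(s$p2p_amp, 100, tolerance = 1)
  # slope = p2p / (peak_time - trough_time); trough at 0.5, peak at 1.25
  expect_equal(s$slope, s$p2p_amp / 0.75, tolerance = 1)
})

test_that("the detector is amplitude-scale equivariant", {
  cfg <- synth_config(duration = 300, noise_seed = 21)
  st <- make_so_train(cfg)
  bg <- make_aperiodic_background(cfg, seed = 22)
  x <- st$signal + bg
  fs <- 200
  e1 <- suppressWarnings(detect_so_events(find_candidates(
    bandpass_so(x, fs), fs)))
  e2 <- suppressWarnings(detect_so_events(find_candidates(
    bandpass_so(3 * x, fs), fs)))
  expect_equal(e1$trough_time, e2$trough_time)
  expect_equal(e2$p2p_amp, 3 * e1$p2p_amp, tolerance = 1e-9)
})

test_that("the amplitude threshold is session-internal", {
  fs <- 200
  mk <- function(base) {
    sig <- unlist(lapply(base + seq(0, 45, by = 5), function(a) {
      tcyc <- seq(0, 1.25, by = 1 / fs)[-1]
      c(-a * sin(2 * pi * tcyc / 1.25), numeric(fs * 0.3))
    }))
    c(numeric(fs), sig, numeric(fs))
  }
  weak <- mk(10); strong <- mk(200)
  # the retained count is percentile-fixed, but pooling shifts the
  # threshold into the strong session, changing *which* events survive
  amps_sep <- c(detect_so_events(find_candidates(weak, fs))$p2p_amp,
                detect_so_events(find_candidates(strong, fs))$p2p_amp)
  pooled <- detect_so_events(find_candidates(c(weak, strong), fs))
  expect_false(setequal(round(amps_sep, 6), round(pooled$p2p_amp, 6)))
  # pooled detection keeps only strong-session cycles
  expect_true(all(pooled$p2p_amp > 2 * 100))
})

test_that("event epochs are trough-centered and boundary-safe", {
  fs <- 200
  sig <- numeric(fs * 300)
  ev <- data.frame(trough_time = c(1, 100, 299.5))
  eps <- extract_event_epochs(sig, ev, fs)
  expect_length(eps, 1)  # events at 1 s and 299.5 s cross the bounds
  expect_equal(attr(eps[[1]], "t0"), 97.5)
  expect_equal(length(eps[[1]]), 5 * fs + 1)
  # events overlapping an avoided span are dropped
  eps2 <- extract_event_epochs(sig, ev, fs,
                               avoid = matrix(c(99, 104), 1))
  expect_length(eps2, 0)
})
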