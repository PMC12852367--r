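fs <- 200
tt5 <- seq(-2.5, 2.5, by = 1 / fs)

test_that("SO phase follows the peak-0/trough-180 convention", {
  # 0.75 Hz cosine with trough at t = 0
  x <- -40 * cos(2 * pi * 0.75 * tt5)
  ph <- so_phase_series(x, fs)
  at <- function(t) ph[which.min(abs(tt5 - t))]
  expect_lt(abs(circ_diff_deg(at(0), 180)), 2)        # trough
  f <- 0.75
  expect_lt(abs(circ_diff_deg(at(1 / (2 * f)), 0)), 2)    # positive peak
  expect_lt(abs(circ_diff_deg(at(1 / (4 * f)), 270)), 5)  # rising midpoint
  expect_lt(abs(circ_diff_deg(at(-1 / (4 * f)), 90)), 5)  # falling midpoint
  expect_error(so_phase_series(numeric(length(tt5)), fs), "undefined")
})

test_that("spindle envelope tracks band-limited amplitude", {
  x13 <- 7 * sin(2 * pi * 13 * tt5)
  env <- spindle_amplitude_series(x13, fs)
  mid <- abs(tt5) < 1.5
  expect_equal(mean(env[mid]), 7, tolerance = 0.35)
  # out-of-band content leaves almost no envelope
  x075 <- 40 * sin(2 * pi * 0.75 * tt5)
  expect_lt(mean(spindle_amplitude_series(x075, fs)[mid]), 0.5)
  # Gaussian burst: envelope max at the burst center
  burst <- exp(-(tt5 - 0.4)^2 / (2 * 0.12^2)) * sin(2 * pi * 13 * tt5)
  envb <- spindle_amplitude_series(burst, fs)
  expect_lt(abs(tt5[which.max(envb)] - 0.4), 0.04)
})

test_that("event-locked PAC reads the planted phase", {
  pac_tr <- event_locked_pac(list(coupling_epoch(180)), fs)
  expect_lt(abs(circ_diff_deg(pac_tr$phases, 180)), 5)
  pac_pk <- event_locked_pac(list(coupling_epoch(360)), fs)
  expect_lt(abs(circ_diff_deg(pac_pk$phases, 0)), 5)
  # recovery of a von Mises population
  set.seed(31)
  phis <- rvonmises(200, 348 * pi / 180, 4) * 180 / pi
  eps <- lapply(phis, coupling_epoch, noise_sd = 2)
  cs <- circular_summary(event_locked_pac(eps, fs))
  expect_lt(abs(circ_diff_deg(cs$mean_angle, 348)), 10)
  expect_gt(cs$R, 0.5)
})

test_that("circular summaries match closed forms", {
  s <- circular_summary(rep(90, 5))
  expect_equal(s$mean_angle, 90)
  expect_equal(s$R, 1)
  sym <- circular_summary(c(0, 90, 180, 270))
  expect_equal(sym$R, 0, tolerance = 1e-12)
  expect_true(is.na(sym$mean_angle))
  two <- circular_summary(c(350, 10))
  expect_equal(two$mean_angle, 0, tolerance = 1e-9)
  expect_equal(two$R, cos(10 * pi / 180), tolerance = 1e-12)
  expect_error(circular_summary(numeric(0)), "empty")
})

test_that("Watson-Williams separates means and respects nulls", {
  set.seed(32)
  g0 <- rvonmises(50, 0, 8) * 180 / pi
  g90 <- rvonmises(50, pi / 2, 8) * 180 / pi
  ww <- watson_williams(list(g0, g90))
  expect_lt(ww$p, 0.001)
  expect_equal(ww$df1, 1)
  expect_equal(ww$df2, 98)
  same <- watson_williams(list(g0, g0))
  expect_lt(same$F, 1e-9)
  expect_error(watson_williams(list(g0, g90[1:3])), "at least 5")
})

test_that("coupling statistics are rotation-equivariant", {
  set.seed(33)
  g1 <- rvonmises(40, 1, 4) * 180 / pi
  g2 <- rvonmises(40, 2, 4) * 180 / pi
  rot <- 73
  s1 <- circular_summary(g1)
  s1r <- circular_summary((g1 + rot) %% 360)
  expect_equal(s1r$R, s1$R, tolerance = 1e-12)
  expect_lt(abs(circ_diff_deg(s1r$mean_angle, s1$mean_angle + rot)), 1e-9)
  w <- watson_williams(list(g1, g2))
  wr <- watson_williams(list((g1 + rot) %% 360, (g2 + rot) %% 360))
  expect_equal(wr$F, w$F, tolerance = 1e-9)
  # PAC is invariant to amplitude scaling of the whole epoch
  ep <- coupling_epoch(210, noise_sd = 1)
  p1 <- event_locked_pac(list(ep), fs)$phases
  p2 <- event_locked_pac(list(5 * ep), fs)$phases
  expect_equal(p1, p2, tolerance = 1e-9)
})
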