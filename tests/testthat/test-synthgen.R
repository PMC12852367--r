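test_that("peak current density matches the protocol arithmetic", {
  expect_equal(signif(peak_current_density(stim_protocol()), 3), 0.507)
  # electrode with 1 cm^2 area: density equals current in mA
  d_unit <- 2 / sqrt(pi) * 10  # mm
  p <- stim_protocol(current_max = 100, electrode_diameter = d_unit)
  expect_equal(peak_current_density(p), 0.1, tolerance = 1e-12)
  p2 <- stim_protocol(electrode_diameter = 16)
  expect_equal(peak_current_density(p2),
               peak_current_density(stim_protocol()) / 4,
               tolerance = 1e-12)
})

test_that("aperiodic background has the requested spectral exponent", {
  cfg0 <- synth_config(duration = 120, aperiodic_exponent = 0,
                       noise_seed = 4)
  f0 <- fit_spectral_slope(welch_psd(make_aperiodic_background(cfg0), 200))
  expect_lt(abs(f0$exponent_x), 0.05)
  cfg2 <- synth_config(duration = 300, aperiodic_exponent = 2,
                       noise_seed = 42)
  bg <- make_aperiodic_background(cfg2)
  expect_lt(abs(mean(bg)), 1e-8)
  f2 <- fit_spectral_slope(welch_psd(bg, 200))
  expect_lt(abs(f2$exponent_x - 2), 0.1)
  # seed determinism: identical bytes
  expect_identical(bg, make_aperiodic_background(cfg2))
  expect_error(synth_config(aperiodic_exponent = NaN), "finite")
})

test_that("SO train plants admissible, recoverable cycles", {
  cfg <- synth_config(duration = 240, so_rate = 0)
  st0 <- make_so_train(cfg)
  expect_identical(st0$signal, numeric(240 * 200))
  expect_length(st0$truth$so_trough_times, 0)

  cfg1 <- synth_config(duration = 300, noise_seed = 11)
  st <- make_so_train(cfg1)
  expect_true(all(st$truth$so_durations >= 0.8 &
                    st$truth$so_durations <= 2))
  expect_equal(length(st$truth$so_trough_times),
               length(st$truth$so_amplitudes))
  # trough sits a quarter cycle after onset
  expect_equal(st$truth$so_trough_times,
               st$truth$so_onsets + st$truth$so_durations / 4)
  expect_error(make_so_train(synth_config(duration = 60, so_rate = 40)),
               "too high")

  # noiseless input: the detector recovers every planted event
  cands <- find_candidates(bandpass_so(st$signal, 200), 200)
  m <- match_planted(cands, st$truth$so_trough_times)
  expect_equal(m$recall, 1)
  expect_lt(m$terr, 0.05)
})

test_that("a planted 0.75 Hz cycle has symmetric 0.667 s half-waves", {
  cfg <- synth_config(duration = 120, so_rate = 2,
                      so_freq_range = c(0.75, 0.75), noise_seed = 2)
  st <- make_so_train(cfg)
  cands <- find_candidates(bandpass_so(st$signal, 200), 200)
  ev <- suppressWarnings(detect_so_events(cands))
  # keep the planted cycles (flank wiggles may add small candidates)
  ev <- ev[vapply(ev$trough_time, function(t)
    min(abs(st$truth$so_trough_times - t)) < 0.2, logical(1)), ]
  expect_gt(nrow(ev), 0)
  expect_equal(mean(ev$neg_halfwave_dur), 2 / 3, tolerance = 0.08)
  expect_equal(mean(ev$pos_halfwave_dur), 2 / 3, tolerance = 0.08)
})

test_that("coupled spindles land at the drawn von Mises phases", {
  cfg <- synth_config(duration = 600, coupling_kappa = 1e6,
                      coupling_mean_phase = 180, coupling_probability = 1,
                      noise_seed = 5)
  st <- make_so_train(cfg)
  sp <- make_coupled_spindles(st$truth, cfg)
  expect_true(all(abs(circ_diff_deg(sp$truth$spindle_phases, 180)) < 0.5))
  # planted burst center time maps to the SO trough for phase 180
  # (kappa = 1e6 draws deviate from 180 by < 0.5 deg, i.e. < 3 ms)
  expect_equal(sp$truth$spindle_times,
               st$truth$so_trough_times[sp$truth$coupled_events],
               tolerance = 3e-3)

  cfg0 <- synth_config(duration = 120, coupling_probability = 0,
                       noise_seed = 5)
  st0 <- make_so_train(cfg0)
  sp0 <- make_coupled_spindles(st0$truth, cfg0)
  expect_identical(sp0$signal, numeric(120 * 200))
})

test_that("kappa = 0 phases are uniform on the circle", {
  set.seed(7)
  draws <- rvonmises(1000, 0, 0) * 180 / pi
  # under uniformity E[R] ~ sqrt(pi)/(2 sqrt(n)) ~ 0.028
  expect_lt(circular_summary(draws)$R, 0.1)
  # concentrated case
  set.seed(8)
  d2 <- rvonmises(500, pi, 50) * 180 / pi
  expect_lt(abs(circ_diff_deg(circular_summary(d2)$mean_angle, 180)), 3)
})

test_that("generated recordings honor the block protocol", {
  cfg <- synth_config(duration = 1200, noise_seed = 9)
  gen <- generate_recording(cfg, stim_protocol(n_blocks = 7))
  ann <- gen$recording$annotations
  blocks <- ann[ann$label == "STIM_BLOCK", ]
  expect_equal(nrow(blocks), 7)
  offs <- blocks$onset + blocks$duration
  gaps <- blocks$onset[-1] - offs[-7]
  expect_true(all(gaps >= 90))
  expect_equal(sum(ann$label == "POST_WINDOW"), 7)
  # artifact off: block spans equal the clean component sum
  cfg0 <- synth_config(duration = 1200, artifact_amp = 0, noise_seed = 9)
  gen0 <- generate_recording(cfg0, stim_protocol(n_blocks = 7))
  i_in <- round(blocks$onset[1] * 200):round(offs[1] * 200)
  expect_false(isTRUE(all.equal(gen$recording$samples["Fz", i_in],
                                gen0$recording$samples["Fz", i_in])))
  i_out <- round((offs[1] + 1) * 200):round((offs[1] + 30) * 200)
  expect_equal(gen$recording$samples["Fz", i_out],
               gen0$recording$samples["Fz", i_out])
  expect_error(
    generate_recording(synth_config(duration = 200),
                       stim_protocol(n_blocks = 7)),
    "too short")
})

test_that("cohort plans validate effects and stay deterministic", {
  expect_error(cohort_plan(4, effects = list(bogus = 1)), "unknown effect")
  p1 <- cohort_plan(4, master_seed = 3)
  p2 <- cohort_plan(4, master_seed = 3)
  expect_identical(p1$cells$seed, p2$cells$seed)
  expect_identical(p1$subjects, p2$subjects)
  # zero effects: identical generating parameters across conditions
  cfgs <- lapply(c("sham", "anodal", "cathodal"), function(cnd)
    sleeposc:::cell_config(p1, "s01", cnd))
  for (f in c("coupling_mean_phase", "aperiodic_exponent", "spindle_amp")) {
    expect_equal(cfgs[[1]][[f]], cfgs[[2]][[f]])
    expect_equal(cfgs[[1]][[f]], cfgs[[3]][[f]])
  }
  # planted effects shift only the targeted condition
  pe <- cohort_plan(4, effects = list(phase_shift = c(anodal = 15),
                                      exponent_shift = c(cathodal = 0.3)),
                    master_seed = 3)
  expect_equal(sleeposc:::cell_config(pe, "s01", "anodal")$coupling_mean_phase,
               sleeposc:::cell_config(pe, "s01", "sham")$coupling_mean_phase
               + 15)
  expect_equal(sleeposc:::cell_config(pe, "s01", "cathodal")$aperiodic_exponent -
                 sleeposc:::cell_config(pe, "s01", "sham")$aperiodic_exponent,
               0.3)
})

test_that("planted MEQ moderation is recovered with the right sign", {
  # negative moderation: anodal spindle gain decreases with MEQ
  hits <- 0L
  for (r in 1:50) {
    plan <- cohort_plan(22, effects = list(
      spindle_amp_shift = c(anodal = 3),
      meq_spindle_slope = c(anodal = -0.4)), master_seed = 1000 + r)
    amp <- vapply(seq_len(22), function(i) {
      s <- plan$subjects$subject[i]
      sleeposc:::cell_config(plan, s, "anodal")$spindle_amp -
        sleeposc:::cell_config(plan, s, "sham")$spindle_amp
    }, numeric(1))
    set.seed(2000 + r)
    tab <- data.frame(
      subject = rep(plan$subjects$subject, 3),
      condition = rep(c("sham", "anodal", "cathodal"), each = 22),
      value = c(rnorm(22, 0, 2), amp + rnorm(22, 0, 2), rnorm(22, 0, 2)),
      meq = rep(plan$subjects$meq, 3))
    fit <- stats::lm(tab$value[tab$condition == "anodal"] -
                       tab$value[tab$condition == "sham"] ~
                       I(tab$meq[tab$condition == "anodal"] - 60))
    hits <- hits + (coef(fit)[2] < 0)
  }
  expect_gte(hits / 50, 0.9)
})
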