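fs <- 200
tt5 <- seq(-2.5, 2.5, by = 1 / fs)

test_that("Morlet maps localize tones and scale quadratically", {
  tf <- morlet_tfr(sin(2 * pi * 15 * tt5), fs)
  expect_equal(length(tf$freqs), 51)
  am <- tf$freqs[apply(tf$power, 1, which.max)]
  expect_true(all(abs(am - 15) <= 0.2 + 1e-9))
  tf2 <- morlet_tfr(2 * sin(2 * pi * 15 * tt5), fs)
  expect_equal(tf2$power, 4 * tf$power, tolerance = 1e-9)
  expect_true(all(tf$times >= -2.35 - 1e-9 & tf$times <= 2.35 + 1e-9))
  expect_error(morlet_tfr(sin(2 * pi * 15 * tt5[1:40]), fs), "shorter")
})

test_that("a burst's power maximum lands at the burst center", {
  burst <- exp(-(tt5 - 0.3)^2 / (2 * 0.1^2)) * sin(2 * pi * 13 * tt5)
  tf <- morlet_tfr(burst, fs)
  i13 <- which.min(abs(tf$freqs - 13))
  expect_lt(abs(tf$times[which.max(tf$power[, i13])] - 0.3), 0.06)
})

test_that("z-score baseline normalizes the baseline window", {
  set.seed(5)
  x <- sin(2 * pi * 13 * tt5) * (tt5 > 0) + rnorm(length(tt5), sd = 0.2)
  tfz <- zscore_baseline(morlet_tfr(x, fs))
  expect_equal(tfz$baseline_state, "zscored")
  rows <- tfz$times >= -2.35 - 1e-9 & tfz$times <= -1.5 + 1e-9
  expect_lt(max(abs(colMeans(tfz$power[rows, ]))), 1e-9)
  expect_equal(unname(apply(tfz$power[rows, ], 2, sd)), rep(1, 51),
               tolerance = 1e-9)
  # burst region clearly positive relative to baseline
  i13 <- which.min(abs(tfz$freqs - 13))
  expect_gt(mean(tfz$power[tfz$times > 0.5 & tfz$times < 1.5, i13]), 2)
  # constant-power epoch gets flagged, not NaN-filled
  flat <- zscore_baseline(morlet_tfr(numeric(length(tt5)), fs))
  expect_true(flat$excluded)
  expect_false(anyNA(flat$power))
})

test_that("paired t maps equal the closed-form paired t", {
  set.seed(6)
  mk_map <- function(p) {
    m <- list(power = p, times = 1:4, freqs = 1:3, excluded = FALSE)
    class(m) <- "tfr_map"
    m
  }
  A <- lapply(1:8, function(i) mk_map(matrix(rnorm(12), 4, 3)))
  B <- lapply(1:8, function(i) mk_map(matrix(rnorm(12), 4, 3)))
  tm <- paired_t_map(A, B)
  d11 <- vapply(1:8, function(i) A[[i]]$power[2, 3] - B[[i]]$power[2, 3],
                numeric(1))
  expect_equal(tm$t_map[2, 3], mean(d11) / (sd(d11) / sqrt(8)),
               tolerance = 1e-12)
  expect_true(all(paired_t_map(A, A)$t_map == 0))
  expect_error(paired_t_map(A[1:3], B[1:4]), "same subjects")
})

test_that("TFCE is monotone, sign-symmetric and localizes effects", {
  m <- matrix(0, 5, 5)
  m[3, 3] <- 1
  v1 <- tfce_transform(m)[3, 3]
  m[3, 3] <- 2
  v2 <- tfce_transform(m)[3, 3]
  expect_gt(v2, v1)
  set.seed(7)
  r <- matrix(rnorm(100), 10, 10)
  expect_equal(tfce_transform(-r), -tfce_transform(r), tolerance = 1e-12)
})

test_that("sign-flip permutation is calibrated and exact for small n", {
  set.seed(8)
  n <- 10
  D <- matrix(rnorm(n * 48), n)
  tm <- list(t_map = matrix(sleeposc:::t_from_diffs(D), 8, 6), diffs = D,
             dims = c(8, 6), times = 1:8, freqs = 1:6, n = n)
  res <- tfce_permutation(tm, tfce_params(n_perm = 256), seed = 3)
  expect_true(all(res$p_map >= 1 / 257))
  expect_true(all(res$p_map <= 1))
  # mask shrinks (or stays) as alpha decreases
  m05 <- sum(res$p_map < 0.05)
  m01 <- sum(res$p_map < 0.01)
  expect_lte(m01, m05)
  # exact enumeration below 2^n <= n_perm is deterministic
  D5 <- matrix(rnorm(5 * 12), 5)
  tm5 <- list(t_map = matrix(sleeposc:::t_from_diffs(D5), 4, 3),
              diffs = D5, dims = c(4, 3), times = 1:4, freqs = 1:3, n = 5)
  expect_warning(r1 <- tfce_permutation(tm5, tfce_params(n_perm = 256),
                                        seed = 1), "enumerat")
  expect_warning(r2 <- tfce_permutation(tm5, tfce_params(n_perm = 256),
                                        seed = 999), "enumerat")
  expect_identical(r1$p_map, r2$p_map)
  expect_true(r1$exact)
})

test_that("a planted patch effect is detected and localized", {
  set.seed(9)
  n <- 22
  nr <- 20; nc <- 12
  patch <- matrix(0, nr, nc)
  patch[6:12, 4:8] <- 2
  D <- t(vapply(seq_len(n), function(i)
    as.numeric(patch + matrix(rnorm(nr * nc), nr, nc)),
    numeric(nr * nc)))
  tm <- list(t_map = matrix(sleeposc:::t_from_diffs(D), nr, nc), diffs = D,
             dims = c(nr, nc), times = 1:nr, freqs = 1:nc, n = n)
  res <- tfce_permutation(tm, tfce_params(n_perm = 512), seed = 5)
  inside <- res$significant_mask[6:12, 4:8]
  outside <- res$significant_mask
  outside[6:12, 4:8] <- FALSE
  expect_gte(mean(inside), 0.5)
  expect_lt(mean(outside), 0.05)
})
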