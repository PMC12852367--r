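test_that("rm-ANOVA reproduces the independent oracle to 4 decimals", {
  # frozen from a multivariate-model computation (car::Anova, type III,
  # idesign ~condition) on the 6-subject fixture
  r <- rm_anova(long_table(oracle_Y()))
  expect_equal(round(r$F, 4), 32.1095)
  expect_equal(round(r$gg_epsilon, 4), 0.8797)
  expect_equal(round(r$p, 4), round(0.0001145954, 4))
  expect_equal(round(r$p_uncorrected, 4), round(4.44045e-05, 4))
  expect_equal(round(r$partial_eta_sq, 4), 0.8653)
  # cross-check against car at run time as a second route
  mlm <- stats::lm(oracle_Y() ~ 1)
  av <- summary(car::Anova(mlm,
                           idata = data.frame(
                             condition = factor(colnames(oracle_Y()),
                                                levels = colnames(oracle_Y()))),
                           idesign = ~condition, type = 3),
                multivariate = FALSE)
  expect_equal(r$F, unname(av$univariate.tests["condition", "F value"]),
               tolerance = 1e-6)
  expect_equal(r$gg_epsilon,
               unname(av$pval.adjustments["condition", "GG eps"]),
               tolerance = 1e-6)
})

test_that("rm-ANOVA invariances hold", {
  Y <- oracle_Y()
  r0 <- rm_anova(long_table(Y))
  # adding a per-subject constant changes nothing
  Yc <- Y + matrix(rep(c(5, -3, 11, 0, 7, -2), 3), 6)
  rc <- rm_anova(long_table(Yc))
  expect_equal(rc$F, r0$F, tolerance = 1e-9)
  expect_equal(rc$gg_epsilon, r0$gg_epsilon, tolerance = 1e-9)
  # identical conditions: F = 0, p = 1
  set.seed(99)
  Yi <- matrix(rep(rnorm(6), 3), 6,
               dimnames = list(sprintf("s%d", 1:6),
                               c("sham", "anodal", "cathodal")))
  ri <- rm_anova(long_table(Yi))
  expect_equal(ri$F, 0)
  expect_equal(ri$p, 1)
  # epsilon bounds for k = 3
  for (seed in 1:10) {
    set.seed(seed)
    Yr <- matrix(rnorm(18), 6,
                 dimnames = list(sprintf("s%d", 1:6),
                                 c("sham", "anodal", "cathodal")))
    e <- rm_anova(long_table(Yr))$gg_epsilon
    expect_gte(e, 0.5)
    expect_lte(e, 1)
  }
  # incomplete subjects are dropped with a warning
  tab <- long_table(Y)[-1, ]
  expect_warning(rm <- rm_anova(tab), "dropped")
  expect_equal(rm$n, 5)
})

test_that("Holm contrasts follow the step-down arithmetic", {
  expect_equal(stats::p.adjust(c(0.010, 0.040), "holm"), c(0.020, 0.040))
  ct <- planned_contrasts_holm(long_table(oracle_Y()))
  expect_equal(round(ct$p_raw, 6), c(0.003180, 0.015359))
  expect_equal(round(ct$p_adj, 6), c(0.006360, 0.015359))
  expect_equal(round(ct$cohens_d, 4), c(2.1656, -1.4743))
  expect_true(all(ct$p_adj >= ct$p_raw))
  # single contrast passes through unadjusted
  one <- planned_contrasts_holm(long_table(oracle_Y()),
                                pairs = list(c("anodal", "sham")))
  expect_equal(one$p_adj, one$p_raw)
  # identical conditions give d = 0
  Y2 <- oracle_Y()
  Y2[, "anodal"] <- Y2[, "sham"]
  d0 <- planned_contrasts_holm(long_table(Y2),
                               pairs = list(c("anodal", "sham")))
  expect_equal(d0$cohens_d, 0)
})

test_that("MEQ classification follows the questionnaire cutoffs", {
  expect_equal(meq_classify(59), "morning")
  expect_equal(meq_classify(86), "morning")
  expect_equal(meq_classify(58), "intermediate_evening")
  expect_equal(meq_classify(42), "intermediate_evening")
  low <- meq_classify(41)
  expect_equal(as.character(low), "intermediate_evening")
  expect_true(attr(low, "below_band"))
  expect_error(meq_classify(15), "16..86")
  expect_error(meq_classify(90), "16..86")
})

test_that("rm-ANCOVA detects planted moderation and rejects degenerate input", {
  # planted interaction: anodal effect decreases with centered MEQ
  hits <- 0L
  for (r in 1:30) {
    set.seed(400 + r)
    n <- 22
    meq <- pmin(pmax(round(rnorm(n, 60, 7)), 16), 86)
    anodal_eff <- 2 - 0.35 * (meq - mean(meq)) + rnorm(n, sd = 2)
    tab <- data.frame(
      subject = rep(sprintf("s%02d", 1:n), 3),
      condition = rep(c("sham", "anodal", "cathodal"), each = n),
      value = c(rnorm(n, sd = 2), anodal_eff, rnorm(n, sd = 2)) +
        rep(rnorm(n), 3),
      meq = rep(meq, 3))
    hits <- hits + (rm_ancova_moderation(tab)$p < 0.05)
  }
  expect_gte(hits / 30, 0.8)
  tab$meq <- 60
  expect_error(rm_ancova_moderation(tab), "no moderator variance")
})

test_that("mixed ANOVA handles groups, ties and imbalance", {
  set.seed(50)
  n <- 12
  Y <- matrix(rnorm(3 * n), n, 3,
              dimnames = list(sprintf("s%02d", 1:n),
                              c("sham", "anodal", "cathodal")))
  # two groups with *identical* data: interaction exactly 0
  Y[7:12, ] <- Y[1:6, ]
  tab <- data.frame(subject = rep(rownames(Y), 3),
                    condition = rep(colnames(Y), each = n),
                    value = as.numeric(Y),
                    chronotype = rep(rep(c("morning", "intermediate_evening"),
                                         each = 6), 3))
  r <- suppressWarnings(mixed_anova_chronotype(tab))
  expect_lt(r$interaction$F, 1e-9)
  expect_equal(unname(r$interaction$df1), 2)
  # unbalanced 12 vs 10 accepted
  set.seed(51)
  n2 <- 22
  Y2 <- matrix(rnorm(3 * n2), n2, 3,
               dimnames = list(sprintf("s%02d", 1:n2),
                               c("sham", "anodal", "cathodal")))
  tab2 <- data.frame(subject = rep(rownames(Y2), 3),
                     condition = rep(colnames(Y2), each = n2),
                     value = as.numeric(Y2),
                     chronotype = rep(rep(c("morning", "intermediate_evening"),
                                          c(12, 10)), 3))
  r2 <- suppressWarnings(mixed_anova_chronotype(tab2))
  expect_equal(sort(unname(as.numeric(r2$group_sizes))), c(10, 12))
  expect_true(is.finite(r2$interaction$F))
  expect_equal(nrow(r2$simple_effects), 4)
  # a planted group-specific anodal effect is detected most of the time
  hits <- 0L
  for (rr in 1:20) {
    set.seed(600 + rr)
    Yp <- matrix(rnorm(3 * n2, sd = 1), n2, 3,
                 dimnames = dimnames(Y2))
    Yp[13:22, "anodal"] <- Yp[13:22, "anodal"] + 2.5
    tabp <- tab2
    tabp$value <- as.numeric(Yp)
    hits <- hits + (suppressWarnings(
      mixed_anova_chronotype(tabp))$interaction$p < 0.05)
  }
  expect_gte(hits / 20, 0.8)
})

test_that("Pearson regression matches its closed forms", {
  x <- c(1, 2, 3.5, 5, 7, 8)
  r <- pearson_regression(x, -x)
  expect_equal(r$r, -1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  set.seed(60)
  a <- rnorm(30); b <- rnorm(30)
  pr <- pearson_regression(a, b)
  expect_equal(pr$r_squared, pr$r^2, tolerance = 1e-15)
  expect_error(pearson_regression(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_regression(1:2, 1:2), "at least 3")
})
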