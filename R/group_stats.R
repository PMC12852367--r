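#' Classify chronotype from an MEQ score
#'
#' Morningness-Eveningness Questionnaire dichotomy: scores of 59 and above
#' are morning types; 42--58 intermediate/evening types. Scores below 42
#' (frank evening types) also map to `intermediate_evening` under the
#' dichotomy and carry a `below_band` attribute flag.
#'
#' @param score integer MEQ score in 16--86
#' @return "morning" or "intermediate_evening"
#' @export
meq_classify <- function(score) {
  if (score < 16 || score > 86) stop("MEQ score must lie in 16..86")
  if (score >= 59) return("morning")
  out <- "intermediate_evening"
  if (score < 42) attr(out, "below_band") <- TRUE
  out
}

# Long table -> complete-case wide matrix (subjects x conditions).
wide_conditions <- function(table, conditions = NULL) {
  stopifnot(all(c("subject", "condition", "value") %in% names(table)))
  if (is.null(conditions)) conditions <- unique(table$condition)
  k <- length(conditions)
  subj <- unique(table$subject)
  Y <- matrix(NA_real_, length(subj), k,
              dimnames = list(subj, conditions))
  for (i in seq_len(nrow(table))) {
    Y[table$subject[i], table$condition[i]] <- table$value[i]
  }
  complete <- stats::complete.cases(Y)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) dropped (incomplete conditions)")
  }
  Y[complete, , drop = FALSE]
}

# Greenhouse-Geisser epsilon from the conditions covariance matrix.
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  Sdc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- sum(diag(Sdc))^2 / ((k - 1) * sum(Sdc^2))
  if (!is.finite(eps)) eps <- 1  # degenerate (constant) input
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F test of a condition effect on complete cases, with the
#' Greenhouse-Geisser sphericity correction applied unconditionally (the
#' uncorrected p is reported alongside) and partial eta squared.
#'
#' @param table long data frame with columns subject, condition, value
#' @return list of class `rm_anova` with `F`, `df1`, `df2`, `p_uncorrected`,
#'   `gg_epsilon`, `df1_gg`, `df2_gg`, `p` (GG-corrected),
#'   `partial_eta_sq`, `n`, `k`
#' @export
rm_anova <- function(table) {
  Y <- wide_conditions(table)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2) stop("need at least 2 conditions")
  if (n < 3) stop("need at least 3 complete subjects")
  gm <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - gm)^2)
  ss_subj <- k * sum((rowMeans(Y) - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fstat <- if (ss_err <= .Machine$double.eps * max(ss_tot, 1)) {
    if (ss_cond <= .Machine$double.eps * max(ss_tot, 1)) 0 else Inf
  } else {
    (ss_cond / df1) / (ss_err / df2)
  }
  eps <- gg_epsilon(Y)
  structure(list(F = Fstat, df1 = df1, df2 = df2,
                 p_uncorrected = stats::pf(Fstat, df1, df2,
                                           lower.tail = FALSE),
                 gg_epsilon = eps,
                 df1_gg = eps * df1, df2_gg = eps * df2,
                 p = stats::pf(Fstat, eps * df1, eps * df2,
                               lower.tail = FALSE),
                 partial_eta_sq = if (ss_cond + ss_err > 0)
                   ss_cond / (ss_cond + ss_err) else 0,
                 n = n, k = k),
            class = "rm_anova")
}

#' Paired Cohen's d
#'
#' `mean(diff) / sd(diff)` for a within-subject contrast.
#'
#' @param a,b paired numeric vectors
#' @return Cohen's d
#' @export
cohens_d_paired <- function(a, b) {
  d <- a - b
  if (stats::sd(d) == 0) return(0)
  mean(d) / stats::sd(d)
}

#' Planned pairwise contrasts with Holm-Bonferroni adjustment
#'
#' Two-tailed paired t-tests for the requested condition pairs, Holm
#' step-down adjustment over the family, and paired Cohen's d per pair.
#' Contrasts are always computed; `omnibus_significant` merely records
#' whether the gating omnibus test passed.
#'
#' @param table long data frame (subject, condition, value)
#' @param pairs list of length-2 character vectors of condition labels
#' @param omnibus_significant logical flag recorded on the result
#' @return data frame with pair, t, df, p_raw, p_adj, cohens_d
#' @export
planned_contrasts_holm <- function(table,
                                   pairs = list(c("cathodal", "sham"),
                                                c("anodal", "sham")),
                                   omnibus_significant = NA) {
  Y <- wide_conditions(table)
  res <- lapply(pairs, function(pr) {
    a <- Y[, pr[1]]; b <- Y[, pr[2]]
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(pair = paste(pr, collapse = "-"),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, cohens_d = cohens_d_paired(a, b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "holm")
  out <- out[, c("pair", "t", "df", "p_raw", "p_adj", "cohens_d")]
  attr(out, "omnibus_significant") <- omnibus_significant
  out
}

#' Repeated-measures ANCOVA: condition x continuous MEQ moderation
#'
#' Tests whether a continuous moderator (MEQ chronotype score, centered
#' before entry) moderates the within-subject condition effect. The
#' interaction F uses the within-subject error stratum with the subject
#' effect absorbed: F with ((k-1), (k-1)(n-2)) df, reported both
#' uncorrected and Greenhouse-Geisser corrected (epsilon from the
#' covariance of the per-condition residuals after removing the covariate
#' regression).
#'
#' @param table long data frame with subject, condition, value, meq
#' @return list of class `rm_ancova` with the interaction test
#' @export
rm_ancova_moderation <- function(table) {
  stopifnot(all(c("subject", "condition", "value", "meq") %in%
                  names(table)))
  meq_by_subj <- tapply(table$meq, table$subject, unique)
  if (any(lengths(meq_by_subj) != 1)) stop("MEQ must be constant per subject")
  Y <- wide_conditions(table)
  n <- nrow(Y); k <- ncol(Y)
  meq <- unlist(meq_by_subj)[rownames(Y)]
  if (stats::sd(meq) == 0) stop("no moderator variance in MEQ")
  mc <- meq - mean(meq)
  long <- data.frame(
    value = as.numeric(Y),
    subject = factor(rep(rownames(Y), k)),
    condition = factor(rep(colnames(Y), each = n)),
    mc = rep(mc, k))
  fit <- stats::lm(value ~ subject + condition + condition:mc, data = long)
  an <- stats::anova(fit)
  i_int <- grep("condition:mc", rownames(an))
  i_res <- nrow(an)
  Fstat <- an[i_int, "Mean Sq"] / an[i_res, "Mean Sq"]
  df1 <- an[i_int, "Df"]; df2 <- an[i_res, "Df"]
  # epsilon from per-condition residuals about the covariate regression
  resid_mat <- apply(Y, 2, function(y) stats::resid(stats::lm(y ~ mc)))
  eps <- gg_epsilon(resid_mat)
  ss_int <- an[i_int, "Sum Sq"]; ss_res <- an[i_res, "Sum Sq"]
  structure(list(F = Fstat, df1 = df1, df2 = df2,
                 p_uncorrected = stats::pf(Fstat, df1, df2,
                                           lower.tail = FALSE),
                 gg_epsilon = eps,
                 p = stats::pf(Fstat, eps * df1, eps * df2,
                               lower.tail = FALSE),
                 partial_eta_sq = ss_int / (ss_int + ss_res),
                 n = n, k = k),
            class = "rm_ancova")
}

#' Mixed ANOVA: within-subject condition x between-subject chronotype
#'
#' Split-plot ANOVA with condition as the within factor and chronotype
#' group as the between factor (type III sums of squares for the
#' unbalanced groups, via a multivariate linear model), reporting the
#' interaction with Greenhouse-Geisser correction plus per-group pairwise
#' condition contrasts.
#'
#' @param table long data frame with subject, condition, value, chronotype
#' @param pairs condition pairs for the per-group simple effects
#' @return list of class `mixed_anova`
#' @export
mixed_anova_chronotype <- function(table,
                                   pairs = list(c("cathodal", "sham"),
                                                c("anodal", "sham"))) {
  stopifnot(all(c("subject", "condition", "value", "chronotype") %in%
                  names(table)))
  Y <- wide_conditions(table)
  grp_by_subj <- tapply(as.character(table$chronotype), table$subject,
                        unique)
  grp <- factor(unlist(grp_by_subj)[rownames(Y)])
  if (nlevels(grp) < 2) stop("need two chronotype groups")
  if (any(table(grp) < 2)) stop("each chronotype group needs n >= 2")
  dat <- data.frame(grp = grp)
  mlm <- stats::lm(Y ~ grp, data = dat,
                   contrasts = list(grp = "contr.sum"))
  idata <- data.frame(condition = factor(colnames(Y),
                                         levels = colnames(Y)))
  av <- car::Anova(mlm, idata = idata, idesign = ~condition, type = 3)
  sm <- summary(av, multivariate = FALSE)
  ut <- sm$univariate.tests
  gg <- sm$pval.adjustments
  pick <- function(tab, name, col) unname(tab[grep(name, rownames(tab),
                                                   fixed = TRUE), col])
  eps <- pick(gg, "condition", "GG eps")[1]
  res <- list(
    interaction = list(
      F = pick(ut, "grp:condition", "F value"),
      df1 = pick(ut, "grp:condition", "num Df"),
      df2 = pick(ut, "grp:condition", "den Df"),
      p_uncorrected = pick(ut, "grp:condition", "Pr(>F)"),
      gg_epsilon = eps,
      p = pick(gg, "grp:condition", "Pr(>F[GG])")),
    condition = list(
      F = pick(ut, "condition", "F value")[1],
      df1 = pick(ut, "condition", "num Df")[1],
      df2 = pick(ut, "condition", "den Df")[1],
      p_uncorrected = pick(ut, "condition", "Pr(>F)")[1],
      p = pick(gg, "condition", "Pr(>F[GG])")[1]),
    group = list(
      F = pick(ut, "grp", "F value")[1],
      df1 = pick(ut, "grp", "num Df")[1],
      df2 = pick(ut, "grp", "den Df")[1],
      p = pick(ut, "grp", "Pr(>F)")[1]),
    group_sizes = table(grp))
  res$simple_effects <- do.call(rbind, lapply(levels(grp), function(g) {
    sub <- Y[grp == g, , drop = FALSE]
    do.call(rbind, lapply(pairs, function(pr) {
      tt <- stats::t.test(sub[, pr[1]], sub[, pr[2]], paired = TRUE)
      data.frame(group = g, pair = paste(pr, collapse = "-"),
                 t = unname(tt$statistic), p = tt$p.value,
                 cohens_d = cohens_d_paired(sub[, pr[1]], sub[, pr[2]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  class(res) <- "mixed_anova"
  res
}

#' Pearson correlation with regression summary
#'
#' @param x,y paired numeric vectors (n >= 3)
#' @return list with `r`, `p`, `r_squared`, `n`
#' @export
pearson_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       r_squared = unname(ct$estimate)^2, n = length(x))
}
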