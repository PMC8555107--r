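#' Two-sample Student's t-test (pooled variance)
#'
#' Pooled-variance (Student, not Welch) two-sample t-test with two-sided
#' p-value, matching the univariate screen applied to log2 fold peptide data.
#' Degenerate inputs (zero pooled variance) are resolved explicitly rather
#' than erroring: equal means give p = 1, unequal means p = 0, with a
#' `degenerate` flag set.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list with `statistic`, `df`, `p`, `degenerate`.
#' @examples
#' student_t_two_sample(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
student_t_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  d <- mean(x) - mean(y)
  if (sp2 <= 0) {
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf, df = df,
                p = if (d == 0) 1 else 0, degenerate = TRUE))
  }
  tstat <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df), degenerate = FALSE)
}

#' Row-wise two-group Student's t screen
#'
#' Vectorized pooled-variance t-test for every row of a feature matrix,
#' with Benjamini-Hochberg adjusted q-values. This is the univariate screen
#' run on the standardized peptide matrix to select group-responsive
#' peptides at a 5% FDR.
#'
#' @param mat numeric matrix, features x workers (no missing values; run
#'   after left-censored imputation).
#' @param groups factor/character of length `ncol(mat)` with two levels.
#' @return data.frame: `feature_id`, `mean_diff` (first level minus second),
#'   `t`, `df`, `p`, `q`.
#' @export
row_t_test <- function(mat, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (length(groups) != ncol(mat)) stop("one group label per column required")
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, !g1, drop = FALSE])
  v1 <- apply(mat[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, !g1, drop = FALSE], 1, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero-variance rows: p = 1 when means agree, 0 otherwise
  degen <- !is.finite(se) | se == 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    tstat[degen] <- ifelse(m1[degen] == m2[degen], 0,
                           sign(m1[degen] - m2[degen]) * Inf)
  }
  data.frame(feature_id = rownames(mat), mean_diff = m1 - m2, t = tstat,
             df = df, p = p, q = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] that keeps the module surface and
#' supports adjusting a subset of p-values against a larger family of `m`
#' tests (the remaining `m - length(p)` tests assumed to have larger p),
#' as needed when the five significant model-vote z-tests are corrected
#' within the full candidate-model family.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param m family size, `>= length(p)`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  if (m < length(p)) stop("family size m must be >= length(p)")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Used to compare breathing-zone exposure metrics (inhalable and respirable
#' elemental carbon, structure counts) between High and Low exposure groups;
#' two fully rank-separated groups of 12 give H = 17.28. Wraps
#' [stats::kruskal.test()] with an explicit guard for the all-identical
#' degenerate case (tie correction denominator zero), which returns H = 0.
#'
#' @param groups list of >= 2 numeric samples.
#' @return list with `statistic` (tie-corrected H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop(">= 2 groups required")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3) stop("total N must be >= 3")
  if (length(unique(pooled)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' One-sample z-test
#'
#' Tests whether a single observed value (here: a model's count of
#' lowest-AICc peptides) departs from a null mean/sd; one-sided upper tail
#' by default, matching the "significance from random" voting test.
#'
#' @param value observed value.
#' @param null_mean,null_sd null distribution moments, `null_sd > 0`.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return list with `statistic` (Z) and `p`.
#' @export
one_sample_z <- function(value, null_mean, null_sd,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.finite(null_sd) || null_sd <= 0) stop("null_sd must be positive")
  z <- (value - null_mean) / null_sd
  p <- switch(alternative,
              greater   = stats::pnorm(z, lower.tail = FALSE),
              less      = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(statistic = z, p = p)
}

#' Power of the two-group design
#'
#' Power of a two-sided pooled-variance two-sample t-test via the noncentral
#' t distribution ([stats::power.t.test()]). Effects are in log2 units, so a
#' two-fold group difference is `effect_log2 = 1`.
#'
#' @param n_per_group workers per group (>= 2).
#' @param effect_log2 group mean difference, log2 units.
#' @param sd_log2 common within-group standard deviation, log2 units. For a
#'   peptide matrix a typical choice is [median_pooled_sd()].
#' @param alpha significance level.
#' @return power, a fraction in \[0, 1\].
#' @export
power_two_group <- function(n_per_group, effect_log2, sd_log2, alpha = 0.05) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (effect_log2 < 0 || sd_log2 <= 0 || alpha <= 0 || alpha >= 1)
    stop("invalid power parameters")
  if (effect_log2 == 0) return(alpha)
  stats::power.t.test(n = n_per_group, delta = effect_log2, sd = sd_log2,
                      sig.level = alpha, type = "two.sample",
                      alternative = "two.sided")$power
}

#' Median per-feature pooled standard deviation
#'
#' Helper supplying a matrix-level `sd_log2` for [power_two_group()]: the
#' median across features of the two-group pooled standard deviation.
#'
#' @param mat numeric matrix, features x workers.
#' @param groups two-level factor over columns.
#' @return scalar standard deviation.
#' @export
median_pooled_sd <- function(mat, groups) {
  groups <- as.factor(groups)
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  v1 <- apply(mat[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, !g1, drop = FALSE], 1, stats::var)
  stats::median(sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)),
                na.rm = TRUE)
}
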