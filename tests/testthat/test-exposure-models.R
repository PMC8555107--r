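test_that("composite exposure is the log10 sum with optional weights", {
  rec <- data.frame(inh_ec = 10, res_ec = 1, struct_count = 0.1)
  expect_equal(make_composite(rec), 0)                    # 1 + 0 - 1
  expect_equal(make_composite(data.frame(inh_ec = 1, res_ec = 1,
                                         struct_count = 1)), 0)
  expect_equal(make_composite(rec, weights = c(2, 1, 1)), 1)
  # strictly increasing in every metric
  up <- make_composite(data.frame(inh_ec = 11, res_ec = 1, struct_count = 0.1))
  expect_gt(up, make_composite(rec))
  expect_error(make_composite(data.frame(inh_ec = 0, res_ec = 1,
                                         struct_count = 1)), "positive")
  expect_equal(make_composite(data.frame(inh_ec = 1e-4, res_ec = 1,
                                         struct_count = 1),
                              loq_floor = NULL), -4)
})

test_that("model enumeration counts combinatorially and rejects duplicates", {
  sp <- enumerate_models(bases = c("logInhEC", "logResEC", "logSC",
                                   "logInhResEC", "logSumExp"),
                         covariates = c("logIL6", "age_bin", "sex",
                                        "duration_bin"),
                         max_covariates = 1)
  expect_equal(nrow(sp), 5 * 5)                 # 5 bases x (empty + 4)
  expect_equal(nrow(enumerate_models()), 280)   # default space
  expect_error(enumerate_models(bases = character(0)), "empty")
  expect_error(enumerate_models(covariates = c("logIL6", "logIL6")),
               "duplicate")
  yaml_path <- system.file("extdata", "models.yaml", package = "peptidomeDx")
  expect_equal(nrow(read_model_space(yaml_path)), 280)
})

test_that("AICc equals the closed form and the lm likelihood oracle", {
  # n = 10, RSS/n = 1, k = 3 -> AIC = 6, AICc = 10: engineered via a
  # response whose regression on x leaves exactly RSS = 10
  set.seed(21)
  x <- scale(rnorm(10), TRUE, FALSE)
  e <- residuals(lm(rnorm(10) ~ x))
  y <- 2 + 3 * x + e * sqrt(10 / sum(e^2))
  f <- fit_aicc(y, matrix(x, ncol = 1))
  expect_equal(f$rss, 10, tolerance = 1e-9)
  expect_equal(f$k, 3)
  expect_equal(f$aic, 6, tolerance = 1e-9)
  expect_equal(f$aicc, 10, tolerance = 1e-9)
  # random instances against the likelihood-based oracle
  for (i in 1:15) {
    n <- sample(8:30, 1); kk <- sample(1:3, 1)
    X <- matrix(rnorm(n * kk), n)
    yy <- rnorm(n)
    f <- fit_aicc(yy, X)
    o <- aic_lm_oracle(yy, X)
    expect_equal(f$aic, o$aic, tolerance = 1e-9)
    expect_equal(f$aicc, o$aicc, tolerance = 1e-9)
    expect_equal(f$adj_r2, o$adj_r2, tolerance = 1e-9)
  }
})

test_that("AICc degenerate cases: constant y, perfect fit, rank deficiency", {
  x <- matrix(rnorm(12), ncol = 1)
  const <- fit_aicc(rep(2, 12), x)
  expect_equal(const$adj_r2, 0)          # zero TSS convention
  perfect <- fit_aicc(drop(2 + 3 * x), x)
  expect_true(perfect$perfect_fit)
  expect_equal(perfect$aicc, -Inf)
  expect_error(fit_aicc(rnorm(12), cbind(x, x)), "rank")
  expect_error(fit_aicc(rnorm(5), matrix(rnorm(15), 5)), "n must exceed")
})

test_that("raw R2 never decreases when adding a predictor", {
  set.seed(31)
  for (i in 1:10) {
    n <- 20
    X1 <- matrix(rnorm(n), ncol = 1)
    X2 <- cbind(X1, rnorm(n))
    y <- rnorm(n)
    r2 <- function(X) 1 - fit_aicc(y, X)$rss / sum((y - mean(y))^2)
    expect_gte(r2(X2), r2(X1) - 1e-12)
  }
})

test_that("vectorized AICc table matches per-peptide fit_aicc", {
  s <- small_synth(seed = 15, n_features = 60, n_responsive = 20,
                   n_top = 5, n_nuisance = 5)
  proc <- preprocess(s$pep$matrix, s$groups, min_frac = 0.5)
  models <- enumerate_models(max_covariates = 1)
  tm <- model_terms(s$cohort)
  tab <- aicc_table(proc, tm, models)
  for (i in c(1, 10, 25)) for (j in c(1, 17, 40)) {
    f <- fit_aicc(proc$values[i, ],
                  tm[colnames(proc$values), models$predictors[[j]],
                     drop = FALSE])
    expect_equal(tab$aicc[i, j], f$aicc, tolerance = 1e-9)
    expect_equal(tab$adj_r2[i, j], f$adj_r2, tolerance = 1e-9)
  }
})

test_that("model voting counts winners, totals and the z/q chain", {
  # three models, five peptides with known winners
  aicc <- cbind(m1 = c(1, 5, 5, 2, 7), m2 = c(2, 1, 6, 3, 6),
                m3 = c(3, 2, 1, 4, 6.5))
  rownames(aicc) <- paste0("p", 1:5)
  v <- vote_models(aicc)
  expect_equal(sum(v$count), 5)                 # delta = 0 partitions
  expect_equal(v$count[v$model_id == "m1"], 2)  # wins p1, p4
  expect_equal(v$count[v$model_id == "m2"], 2)  # wins p2, p5
  expect_equal(v$count[v$model_id == "m3"], 1)  # wins p3
  # all-equal scores: ties split equally -> uniform counts, z = 0
  tie <- matrix(1, 4, 3, dimnames = list(paste0("p", 1:4), paste0("m", 1:3)))
  vt <- vote_models(tie)
  expect_equal(vt$count, rep(4 / 3, 3))
  expect_equal(vt$z, rep(0, 3))
  expect_equal(sum(vt$count), 4)
  # delta tolerance admits co-winners
  vd <- vote_models(aicc, delta = 1)
  expect_true(sum(vd$count) >= 5)
  expect_error(vote_models(aicc[, 1:2]), "3 models")
  # worked vote example: counts {10,2,2,3,3} -> z = 1.77 for the winner
  counts <- c(10, 2, 2, 3, 3)
  z <- (counts[1] - mean(counts)) / sd(counts)
  expect_equal(round(z, 2), 1.77)
})

test_that("voting is invariant to peptide order and per-peptide monotone shifts", {
  set.seed(41)
  aicc <- matrix(rnorm(200), 40, 5,
                 dimnames = list(paste0("p", 1:40), paste0("m", 1:5)))
  v1 <- vote_models(aicc)
  v2 <- vote_models(aicc[sample(40), ])
  expect_equal(v1[order(v1$model_id), ], v2[order(v2$model_id), ],
               ignore_attr = TRUE)
  shifted <- aicc + rnorm(40)          # per-peptide additive shift
  v3 <- vote_models(shifted)
  expect_equal(v1[order(v1$model_id), ], v3[order(v3$model_id), ],
               ignore_attr = TRUE)
})

test_that("correlation filter tiers peptides and intersects strong sets", {
  adj <- cbind(mA = c(0.9, 0.75, 0.5, 0.2), mB = c(0.85, 0.65, 0.45, 0.8))
  rownames(adj) <- paste0("p", 1:4)
  cf <- correlation_filter(adj)
  expect_equal(cf$strong$mA, c("p1", "p2"))
  expect_equal(cf$strong$mB, c("p1", "p4"))
  expect_equal(cf$common, "p1")
  expect_equal(cf$counts$moderate, c(3, 4))
  # intersection of identical sets is the set
  cf2 <- correlation_filter(cbind(adj[, 1, drop = FALSE], adj[, 1]))
  expect_equal(cf2$common, c("p1", "p2"))
})

test_that("planted strong peptides classify strong; noise peptides do not", {
  set.seed(51)
  n <- 24
  x <- c(rnorm(12, 3), rnorm(12, 0))
  strong_hits <- noise_hits <- 0
  for (i in 1:200) {
    y_strong <- x + rnorm(n, sd = sqrt(var(x) * (1 - 0.9) / 0.9))
    y_noise <- rnorm(n)
    X <- matrix(x, ncol = 1)
    strong_hits <- strong_hits + (fit_aicc(y_strong, X)$adj_r2 >= 0.7)
    noise_hits <- noise_hits + (fit_aicc(y_noise, X)$adj_r2 >= 0.7)
  }
  expect_gt(strong_hits / 200, 0.95)
  expect_lt(noise_hits / 200, 0.01)
})
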