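sim_two_class <- function(n = 24, p = 10, gap = 2, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("High", "Low"), each = n / 2), levels = c("High", "Low"))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("w%02d", 1:n), sprintf("f%02d", 1:p)))
  X[y == "High", 1:3] <- X[y == "High", 1:3] + gap
  list(X = X, y = y)
}

test_that("PLS-DA structure: orthogonal scores, unit weights, separation", {
  d <- sim_two_class(gap = 4, seed = 2)
  fit <- fit_plsda(d$X, d$y, n_components = 2)
  expect_equal(colSums(fit$W^2), rep(1, 2), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_lt(abs(crossprod(fit$Tm[, 1], fit$Tm[, 2])), 1e-8)
  # component-1 scores separate the classes by sign
  s1 <- fit$Tm[, 1]
  expect_true(all(sign(s1[d$y == "High"]) != sign(s1[d$y == "Low"])) ||
                all(s1[d$y == "High"] < min(s1[d$y == "Low"])) ||
                all(s1[d$y == "High"] > max(s1[d$y == "Low"])))
  expect_error(fit_plsda(d$X, rep("High", 24)), "two classes")
  expect_warning(fit_plsda(cbind(d$X, const = 1), d$y), "zero-variance")
})

test_that("first NIPALS weight equals the dominant eigenvector of X'yy'X", {
  d <- sim_two_class(seed = 3)
  Xs <- scale(d$X)
  ys <- as.numeric(d$y) - 1 - mean(as.numeric(d$y) - 1)
  M <- crossprod(Xs, ys) %*% t(crossprod(Xs, ys))   # X'y y'X
  ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
  fit <- fit_plsda(d$X, d$y, n_components = 1)
  w <- fit$W[, 1]
  expect_equal(abs(sum(w * ev)), 1, tolerance = 1e-6)
})

test_that("single perfectly separating feature drives prediction", {
  set.seed(4)
  y <- factor(rep(c("High", "Low"), each = 6), levels = c("High", "Low"))
  X <- cbind(sep = c(rnorm(6, 10), rnorm(6, 0)),
             junk = rnorm(12))
  rownames(X) <- sprintf("w%02d", 1:12)
  fit <- fit_plsda(X, y, n_components = 1)
  pr <- predict(fit, X)
  expect_equal(as.character(pr$class), as.character(y))
})

test_that("VIP closed form, normalization and duplicate symmetry", {
  # one component with weights (0.8, 0.6) -> VIP (1.1314, 0.8485)
  fake <- structure(list(W = matrix(c(0.8, 0.6), 2), ssy = 1,
                         feature_names = c("a", "b")),
                    class = "plsda_model")
  v <- vip_scores(fake)
  expect_equal(v$vip[v$feature_id == "a"], 1.131371, tolerance = 1e-6)
  expect_equal(v$vip[v$feature_id == "b"], 0.848528, tolerance = 1e-6)
  # equal weights -> all VIP 1
  eq <- structure(list(W = matrix(rep(0.5, 4), 4), ssy = 1,
                       feature_names = letters[1:4]),
                  class = "plsda_model")
  expect_equal(vip_scores(eq)$vip, rep(1, 4))
  # sum VIP^2 = p on random fits; duplicated features share a VIP
  for (seed in 1:5) {
    d <- sim_two_class(p = 8, seed = seed)
    fit <- fit_plsda(d$X, d$y, n_components = 2)
    v <- vip_scores(fit)
    expect_equal(sum(v$vip^2), 8, tolerance = 1e-8)
  }
  d <- sim_two_class(p = 6, seed = 9)
  Xd <- cbind(d$X, dup = d$X[, 1])
  fit <- suppressWarnings(fit_plsda(Xd, d$y, n_components = 2))
  v <- vip_scores(fit)
  expect_equal(v$vip[v$feature_id == "f01"], v$vip[v$feature_id == "dup"],
               tolerance = 1e-10)
})

test_that("VIP selection applies the cutoff and top-k truncation", {
  vips <- data.frame(feature_id = letters[1:5],
                     vip = c(1.8, 1.2, 1.0, 0.9, 0.2))
  expect_equal(select_discriminant(vips)$feature_id, c("a", "b", "c"))
  expect_equal(select_discriminant(vips, top_k = 2)$feature_id, c("a", "b"))
  expect_equal(nrow(select_discriminant(vips, cutoff = 2)), 0)
})

test_that("cross-validation: exact predictions give Q2 = 1, mean gives Q2 = 0", {
  # direct checks of the PRESS/TSS definition used by cross_validate
  y <- c(0, 0, 1, 1)
  expect_equal(1 - sum((y - y)^2) / sum((y - mean(y))^2), 1)
  pred_mean <- rep(mean(y), 4)
  expect_equal(1 - sum((pred_mean - y)^2) / sum((y - mean(y))^2), 0)
  # near-noiseless separable data: accuracy 1, Q2 ~ 1 under both schemes
  d <- sim_two_class(gap = 8, seed = 5)
  for (scheme in c("monte_carlo", "leave_one_out")) {
    cv <- cross_validate(d$X, d$y, features = sprintf("f%02d", 1:3),
                         scheme = scheme, n_repeats = 30, seed = 6)
    expect_equal(cv$accuracy, 1.0)
    expect_gt(cv$q2, 0.9)
    expect_lte(cv$q2, 1)
  }
})

test_that("random X orthogonal to y gives non-positive expected Q2", {
  set.seed(7)
  q2 <- replicate(20, {
    y <- factor(rep(c("High", "Low"), each = 10))
    X <- matrix(rnorm(20 * 5), 20)
    colnames(X) <- paste0("f", 1:5)
    rownames(X) <- paste0("w", 1:20)
    cross_validate(X, y, n_repeats = 25, seed = sample(1e6, 1))$q2
  })
  expect_lt(mean(q2), 0)
})

test_that("label permutation drives CV accuracy to chance", {
  set.seed(8)
  y <- factor(rep(c("High", "Low"), each = 12))
  X <- matrix(rnorm(24 * 10), 24,
              dimnames = list(paste0("w", 1:24), paste0("f", 1:10)))
  acc <- replicate(50, {
    yp <- sample(y)
    cross_validate(X, yp, n_repeats = 20, seed = sample(1e6, 1))$accuracy
  })
  expect_lt(abs(mean(acc) - 0.5), 0.15)
})

test_that("class probabilities are the clipped linear map of predictions", {
  d <- sim_two_class(gap = 6, seed = 10)
  fit <- fit_plsda(d$X, d$y, n_components = 1)
  pr <- predict(fit, d$X)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_equal(pr$prob, pmin(1, pmax(0, pr$y_hat)))
  # High is coded 0: High workers get low probability of the Low class
  expect_true(all(pr$prob[d$y == "High"] < 0.5))
  expect_true(all(pr$prob[d$y == "Low"] > 0.5))
})

test_that("split-sample validation classifies separable data perfectly", {
  d <- sim_two_class(gap = 8, seed = 11)
  val <- validate_split(d$X, d$y, n_repeats = 25, seed = 12)
  expect_equal(val$n_misclassified, 0)
  expect_equal(val$accuracy, 1)
  probs <- val$class_probabilities
  expect_true(all(probs$mean_prob[probs$group == "Low"] > 0.5))
})

test_that("PCA variance fractions: diagonal case, sum, rotation invariance", {
  set.seed(13)
  n <- 2000
  X <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 1))
  fr <- pca_variance(X)$fractions
  expect_equal(fr, c(0.9, 0.1), tolerance = 0.02)
  expect_equal(sum(fr), 1)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(pca_variance(X %*% R)$fractions, fr, tolerance = 1e-10)
  expect_error(pca_variance(matrix(1, 5, 3)), "variance")
})

test_that("in-package PLS-DA agrees with an independent implementation", {
  library(mixOmics)
  d <- sim_two_class(n = 24, p = 12, gap = 3, seed = 14)
  mine <- fit_plsda(d$X, d$y, n_components = 2)
  ref <- mixOmics::plsda(d$X, d$y, ncomp = 2, scale = TRUE)
  # same latent direction up to sign
  expect_gt(abs(cor(mine$Tm[, 1], ref$variates$X[, 1])), 0.9999)
  # VIP rankings coincide on the first component
  v_mine <- vip_scores(fit_plsda(d$X, d$y, n_components = 1))
  v_ref <- mixOmics::vip(ref)[, 1]
  ord <- v_mine$feature_id
  expect_gt(cor(v_mine$vip, v_ref[ord], method = "spearman"), 0.999)
})
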