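#' Fit a PLS-DA model (NIPALS)
#'
#' Partial least squares discriminant analysis for a two-class response.
#' The class is coded 0/1 and centered; features are autoscaled (centered,
#' unit variance; zero-variance features dropped with a warning). With a
#' single response column the NIPALS iteration converges in one pass, so
#' each component is computed in its closed form: weight
#' `w = X'y / ||X'y||`, score `t = X w`, X-loading `p = X't / t't`,
#' y-loading `q = y't / t't`, followed by deflation of X and y. Scores of
#' distinct components are orthogonal and weight vectors unit-norm.
#'
#' @param X numeric matrix, workers x features.
#' @param y two-level factor/character of worker groups (first level of
#'   `factor(y)` is coded 0).
#' @param n_components number of latent components (default 2).
#' @param center,scale. autoscaling switches (default both on).
#' @return object of class `plsda_model`: weights `W`, loadings `P`,
#'   scores `Tm`, y-loadings `q`, per-component explained-Y sum of squares
#'   `ssy`, regression vector `B` (on the scaled space), scaling constants,
#'   class levels and coding.
#' @export
fit_plsda <- function(X, y, n_components = 2, center = TRUE, scale. = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("PLS-DA here requires exactly two classes")
  if (min(table(y)) < 2) stop("need >= 2 workers per class")
  if (length(y) != nrow(X)) stop("one label per row of X")
  x_means <- if (center) colMeans(X) else rep(0, ncol(X))
  x_sds <- if (scale.) apply(X, 2, stats::sd) else rep(1, ncol(X))
  keep <- x_sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped")
    X <- X[, keep, drop = FALSE]
    x_means <- x_means[keep]; x_sds <- x_sds[keep]
  }
  Xs <- sweep(sweep(X, 2, x_means), 2, x_sds, `/`)
  y01 <- as.numeric(y) - 1
  y_mean <- mean(y01)
  ys <- y01 - y_mean
  p <- ncol(Xs); n <- nrow(Xs)
  A <- min(n_components, p, n - 1)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- ssy <- numeric(A)
  Xd <- Xs; yd <- ys
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    pa <- drop(crossprod(Xd, tt)) / t2
    qa <- sum(yd * tt) / t2
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tt
    q[a] <- qa
    ssy[a] <- qa^2 * t2              # Y sum of squares captured by comp a
    Xd <- Xd - tcrossprod(tt, pa)
    yd <- yd - qa * tt
  }
  if (A < 1) stop("response carries no signal in X")
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]; ssy <- ssy[seq_len(A)]
  B <- W %*% solve(crossprod(P, W), q)   # y ~ Xs regression vector
  structure(list(W = W, P = P, Tm = Tm, q = q, ssy = ssy, B = drop(B),
                 x_means = x_means, x_sds = x_sds,
                 feature_names = colnames(Xs),
                 y_mean = y_mean, classes = levels(y),
                 n_components = A),
            class = "plsda_model")
}

#' Predict from a PLS-DA model
#'
#' Continuous prediction on the 0/1 class coding, hard class call (nearest
#' coded value) and a class probability obtained by linearly mapping the
#' continuous prediction onto \[0, 1\] between the two coded values,
#' clipped at the ends (a deterministic, monotone mapping).
#'
#' @param object a `plsda_model`.
#' @param newdata workers x features matrix with the model's features.
#' @param ... unused.
#' @return data.frame `y_hat`, `prob` (probability of the second class),
#'   `class`.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  Xs <- sweep(sweep(newdata, 2, object$x_means), 2, object$x_sds, `/`)
  y_hat <- drop(Xs %*% object$B) + object$y_mean
  prob <- pmin(1, pmax(0, y_hat))
  data.frame(y_hat = y_hat, prob = prob,
             class = factor(object$classes[1 + (y_hat >= 0.5)],
                            levels = object$classes),
             stringsAsFactors = FALSE)
}

#' Variable importance in projection (VIP)
#'
#' Per-feature contribution to the discriminant model:
#' `VIP_j = sqrt( p * sum_a[ ssy_a (w_aj / ||w_a||)^2 ] / sum_a ssy_a )`,
#' the weighted sum over components of squared normalized weights, scaled
#' so the squared scores average to 1 over the `p` features
#' (`sum VIP^2 = p`). Scores of at least 1.0 mark above-average
#' contributors, the conventional biomarker selection cutoff.
#'
#' @param model a `plsda_model`.
#' @return data.frame `feature_id`, `vip`, sorted by decreasing VIP.
#' @export
vip_scores <- function(model) {
  if (sum(model$ssy) <= 0) stop("model explains no Y variance")
  W2 <- sweep(model$W, 2, sqrt(colSums(model$W^2)), `/`)^2
  p <- nrow(W2)
  vip <- sqrt(p * drop(W2 %*% model$ssy) / sum(model$ssy))
  ids <- model$feature_names %||% sprintf("f%04d", seq_len(p))
  out <- data.frame(feature_id = ids, vip = vip, stringsAsFactors = FALSE)
  out[order(-out$vip), ]
}

#' Select discriminant peptides by VIP
#'
#' @param vips data.frame from [vip_scores()].
#' @param cutoff minimum VIP score (default 1.0).
#' @param top_k optional truncation to the k highest-VIP peptides.
#' @return data.frame of selected peptides, sorted by decreasing VIP.
#' @export
select_discriminant <- function(vips, cutoff = 1.0, top_k = NULL) {
  sel <- vips[vips$vip >= cutoff, , drop = FALSE]
  sel <- sel[order(-sel$vip), , drop = FALSE]
  if (!is.null(top_k)) sel <- utils::head(sel, top_k)
  sel
}

#' Cross-validate a PLS-DA feature model
#'
#' Leave-one-out or Monte-Carlo leave-n-out cross-validation. Every fold
#' refits the PLS-DA model on the training workers only — feature
#' centering and scaling are recomputed inside the fold, so no information
#' leaks from held-out workers. Reported metrics: classification
#' `accuracy` (correct / total held-out predictions), training `r2`
#' (fit of the final full-data model), and the cross-validated
#' `q2 = 1 - PRESS / TSS` with TSS taken about the training-fold means.
#' Per-subject average class probabilities aggregate over the folds in
#' which each worker was held out.
#'
#' @param X workers x features matrix.
#' @param y two-level worker groups.
#' @param features optional feature-id subset (e.g. the top-5 VIP model).
#' @param scheme `"monte_carlo"` (default) or `"leave_one_out"`.
#' @param n_repeats Monte-Carlo repeats (default 50).
#' @param holdout held-out workers per Monte-Carlo repeat (default 4).
#' @param n_components PLS components.
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return object of class `cv_report`: `scheme`, `n_folds`, `accuracy`,
#'   `r2`, `q2`, `class_probabilities` (per-subject mean probability of
#'   the second class plus assignment counts), `skipped` folds.
#' @export
cross_validate <- function(X, y, features = NULL,
                           scheme = c("monte_carlo", "leave_one_out"),
                           n_repeats = 50, holdout = 4, n_components = 2,
                           seed = 1) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- factor(y)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  n <- nrow(X)
  folds <- if (scheme == "leave_one_out") {
    as.list(seq_len(n))
  } else {
    if (holdout >= n - 1) stop("holdout leaves no training data")
    set.seed(seed)
    lapply(seq_len(n_repeats), function(i) sample(n, holdout))
  }
  press <- tss <- 0
  correct <- total <- 0
  prob_sum <- prob_n <- stats::setNames(numeric(n), rownames(X))
  skipped <- 0L
  y01 <- as.numeric(y) - 1
  for (idx in folds) {
    tr <- setdiff(seq_len(n), idx)
    if (length(unique(y[tr])) < 2) { skipped <- skipped + 1L; next }
    fit <- tryCatch(
      suppressWarnings(fit_plsda(X[tr, , drop = FALSE], y[tr],
                                 n_components = n_components)),
      error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    pr <- predict(fit, X[idx, , drop = FALSE])
    press <- press + sum((pr$y_hat - y01[idx])^2)
    tss <- tss + sum((y01[idx] - mean(y01[tr]))^2)
    correct <- correct + sum(pr$class == y[idx])
    total <- total + length(idx)
    prob_sum[idx] <- prob_sum[idx] + pr$prob
    prob_n[idx] <- prob_n[idx] + 1
  }
  if (total == 0) stop("all cross-validation folds were degenerate")
  full <- suppressWarnings(fit_plsda(X, y, n_components = n_components))
  y_fit <- predict(full, X)$y_hat
  r2 <- 1 - sum((y_fit - y01)^2) / sum((y01 - mean(y01))^2)
  probs <- data.frame(
    worker_id = rownames(X) %||% as.character(seq_len(n)),
    group = y,
    mean_prob = ifelse(prob_n > 0, prob_sum / prob_n, NA_real_),
    n_heldout = prob_n, stringsAsFactors = FALSE)
  structure(list(scheme = scheme, n_folds = length(folds),
                 accuracy = correct / total, r2 = r2,
                 q2 = 1 - press / tss,
                 class_probabilities = probs, skipped = skipped),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "cv_report [%s, %d folds%s]: accuracy %.4f  R2 %.5f  Q2 %.5f\n",
    x$scheme, x$n_folds,
    if (x$skipped) sprintf(", %d skipped", x$skipped) else "",
    x$accuracy, x$r2, x$q2))
  invisible(x)
}

#' Split-sample validation with class probabilities
#'
#' Builds the discriminant model on a random half of the workers
#' (stratified by group) and classifies the held-out half across
#' `n_repeats` random sub-samplings, mirroring a separate validation
#' cohort: per-subject average class probabilities and the misclassified
#' count.
#'
#' @param X workers x features matrix.
#' @param y two-level worker groups.
#' @param features optional feature-id subset.
#' @param n_repeats random sub-samplings (default 50).
#' @param n_components PLS components.
#' @param seed RNG seed.
#' @return list with `class_probabilities` (per-subject mean held-out
#'   probability of the second class), `accuracy`, `n_misclassified`.
#' @export
validate_split <- function(X, y, features = NULL, n_repeats = 50,
                           n_components = 2, seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  set.seed(seed)
  n <- nrow(X)
  prob_sum <- prob_n <- stats::setNames(numeric(n), rownames(X))
  correct <- total <- 0
  for (r in seq_len(n_repeats)) {
    tr <- unlist(lapply(split(seq_len(n), y), function(ix)
      sample(ix, floor(length(ix) / 2))))
    te <- setdiff(seq_len(n), tr)
    fit <- suppressWarnings(fit_plsda(X[tr, , drop = FALSE], y[tr],
                                      n_components = n_components))
    pr <- predict(fit, X[te, , drop = FALSE])
    prob_sum[te] <- prob_sum[te] + pr$prob
    prob_n[te] <- prob_n[te] + 1
    correct <- correct + sum(pr$class == y[te])
    total <- total + length(te)
  }
  list(class_probabilities = data.frame(
         worker_id = rownames(X) %||% as.character(seq_len(n)),
         group = y,
         mean_prob = ifelse(prob_n > 0, prob_sum / prob_n, NA_real_),
         stringsAsFactors = FALSE),
       accuracy = correct / total,
       n_misclassified = total - correct)
}

#' Unsupervised PCA variance decomposition
#'
#' Centered (class-blind) principal component analysis used to confirm
#' that group separation is a latent property of the data rather than an
#' artifact of supervised selection: per-component explained-variance
#' fractions (summing to 1) and worker scores.
#'
#' @param X workers x features matrix.
#' @return list with `fractions` and `scores` (workers x components).
#' @export
pca_variance <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need >= 2 workers")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) stop("constant matrix has no variance to decompose")
  list(fractions = v / sum(v), scores = pc$x)
}
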