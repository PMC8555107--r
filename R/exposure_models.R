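#' Composite exposure value
#'
#' Combines personal breathing-zone metrics into a single composite value
#' per worker: the equal-weight sum of log10-transformed metrics (the
#' "log-sum exposure"). A weight vector turns it into a weighted log-linear
#' combination.
#'
#' @param records worker data.frame (from [generate_cohort()] /
#'   [read_workers()]) or any data.frame holding the metric columns.
#' @param metrics metric column names to combine (default all three:
#'   inhalable EC, respirable EC, structure count).
#' @param weights optional numeric weights, one per metric (default equal).
#' @param loq_floor optional positive floor substituted for non-positive
#'   metric values (default none: non-positive values error).
#' @return numeric vector, one composite value per row of `records`.
#' @export
make_composite <- function(records,
                           metrics = c("inh_ec", "res_ec", "struct_count"),
                           weights = NULL, loq_floor = NULL) {
  if (!all(metrics %in% names(records)))
    stop("missing metric columns: ",
         paste(setdiff(metrics, names(records)), collapse = ", "))
  m <- as.matrix(records[, metrics, drop = FALSE])
  if (!is.null(loq_floor)) m[m <= 0] <- loq_floor
  if (any(m <= 0)) stop("exposure metrics must be strictly positive")
  if (is.null(weights)) weights <- rep(1, length(metrics))
  if (length(weights) != length(metrics)) stop("one weight per metric")
  drop(log10(m) %*% weights)
}

# term vocabulary: each term maps a worker table to one numeric column
.term_builders <- list(
  logInhEC     = function(w) log10(w$inh_ec),
  logResEC     = function(w) log10(w$res_ec),
  logSC        = function(w) log10(w$struct_count),
  logInhResEC  = function(w) make_composite(w, c("inh_ec", "res_ec")),
  logSumExp    = function(w) make_composite(w),
  logIL6       = function(w) w$scip_IL6,
  logCCL2      = function(w) w$scip_CCL2,
  logTNFalpha  = function(w) w$scip_TNFalpha,
  logVCAM      = function(w) w$scip_VCAM,
  logICAM      = function(w) w$scip_ICAM,
  age_bin      = function(w) as.numeric(w$age_bin),
  duration_bin = function(w) as.numeric(w$duration_bin),
  sex          = function(w) as.numeric(w$sex == "F"),
  solvent_current = function(w) as.numeric(w$solvent_current),
  solvent_past    = function(w) as.numeric(w$solvent_past)
)

#' Worker-level predictor terms
#'
#' Evaluates the model-term vocabulary on a worker table: single-metric log
#' exposures (`logInhEC`, `logResEC`, `logSC`), the two- and three-metric
#' composites (`logInhResEC`, `logSumExp`), the five SCIP covariates, and
#' demographic/history covariates (`age_bin`, `duration_bin`, `sex`,
#' `solvent_current`, `solvent_past`).
#'
#' @param records worker data.frame.
#' @param terms term names to evaluate (default: all known terms).
#' @return numeric matrix, workers x terms, rownames = worker ids.
#' @export
model_terms <- function(records, terms = names(.term_builders)) {
  unknown <- setdiff(terms, names(.term_builders))
  if (length(unknown)) stop("unknown terms: ", paste(unknown, collapse = ", "))
  tm <- vapply(terms, function(t) .term_builders[[t]](records),
               numeric(nrow(records)))
  rownames(tm) <- records$worker_id
  tm
}

#' Enumerate candidate linear models
#'
#' Builds the candidate model space deterministically: every base exposure
#' variant crossed with every covariate subset up to `max_covariates`
#' terms (including the empty subset). The published family of 237 models
#' is not exactly reconstructible from its description, so the enumeration
#' is configurable and the family size used for multiplicity correction in
#' [vote_models()] can be set independently.
#'
#' @param bases character vector of base exposure terms.
#' @param covariates covariate term pool.
#' @param max_covariates maximum covariate subset size (default 2).
#' @return data.frame with `model_id`, `predictors` (list column of
#'   character vectors), `k_coef` (number of non-intercept coefficients).
#' @export
enumerate_models <- function(bases = c("logInhEC", "logResEC", "logSC",
                                       "logInhResEC", "logSumExp"),
                             covariates = c("logIL6", "logCCL2",
                                            "logTNFalpha", "logVCAM",
                                            "logICAM", "age_bin",
                                            "duration_bin", "sex",
                                            "solvent_current",
                                            "solvent_past"),
                             max_covariates = 2) {
  if (!length(bases)) stop("empty model space")
  if (anyDuplicated(c(bases)) || anyDuplicated(covariates))
    stop("duplicate predictor terms")
  subsets <- list(character(0))
  for (k in seq_len(max_covariates))
    if (k <= length(covariates))
      subsets <- c(subsets, utils::combn(covariates, k, simplify = FALSE))
  preds <- unlist(lapply(bases, function(b)
    lapply(subsets, function(s) c(b, s))), recursive = FALSE)
  ids <- vapply(preds, paste, character(1), collapse = "+")
  if (anyDuplicated(ids)) stop("duplicate models in enumeration")
  out <- data.frame(model_id = ids, stringsAsFactors = FALSE)
  out$predictors <- preds
  out$k_coef <- lengths(preds)
  out
}

#' Read a model space from YAML
#'
#' The YAML file lists `bases`, `covariates` and `max_covariates`; see
#' `system.file("extdata", "models.yaml", package = "peptidomeDx")` for the
#' shipped default.
#'
#' @param path YAML file path.
#' @return model data.frame as from [enumerate_models()].
#' @export
read_model_space <- function(path) {
  sp <- yaml::read_yaml(path)
  enumerate_models(bases = unlist(sp$bases),
                   covariates = unlist(sp$covariates),
                   max_covariates = sp$max_covariates %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordinary least squares with small-sample AIC scoring
#'
#' Fits `y ~ X` by OLS and reports the likelihood-based information
#' criteria with additive constants dropped:
#' `AIC = n log(RSS/n) + 2k` with `k` counting all estimated parameters
#' (regression coefficients, intercept, and the residual variance), and
#' `AICc = AIC + 2k(k+1) / (n - k - 1)`. The adjusted coefficient of
#' determination uses the coefficient count only:
#' `1 - (RSS/(n - k_coef - 1)) / (TSS/(n - 1))`.
#'
#' @param y numeric response (peptide log2-fold vector over workers).
#' @param X numeric predictor matrix (no intercept column; one is added).
#' @return list with `rss`, `k` (total parameters), `aic`, `aicc`,
#'   `adj_r2`, `coef`. `RSS = 0` yields an `-Inf` AICc sentinel with a
#'   `perfect_fit` flag; `n <= k + 1` or rank deficiency errors.
#' @export
fit_aicc <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(Xi)
  if (qr_$rank < ncol(Xi)) stop("rank-deficient predictor matrix")
  k_coef <- ncol(X)
  k <- k_coef + 2L               # + intercept + residual variance
  if (n <= k + 1) stop("n must exceed k + 1 for AICc")
  res <- qr.resid(qr_, y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  adj_r2 <- if (tss == 0) 0 else
    1 - (rss / (n - k_coef - 1)) / (tss / (n - 1))
  # numerically perfect fits (RSS at rounding level) get the -Inf sentinel
  if (rss <= 1e-12 * max(tss, .Machine$double.eps)) {
    return(list(rss = 0, k = k, aic = -Inf, aicc = -Inf, adj_r2 = adj_r2,
                coef = qr.coef(qr_, y), perfect_fit = TRUE))
  }
  aic <- n * log(rss / n) + 2 * k
  list(rss = rss, k = k, aic = aic,
       aicc = aic + 2 * k * (k + 1) / (n - k - 1),
       adj_r2 = adj_r2, coef = qr.coef(qr_, y), perfect_fit = FALSE)
}

#' Score every peptide under every candidate model
#'
#' Vectorized AICc scoring: for each candidate model the design matrix is
#' factorized once and residual sums of squares are obtained for all
#' peptides jointly.
#'
#' @param mat standardized peptide matrix (features x workers) or
#'   [quant_matrix()].
#' @param term_matrix workers x terms matrix from [model_terms()].
#' @param models model data.frame from [enumerate_models()].
#' @return list with `aicc` and `adj_r2` matrices (features x models).
#' @export
aicc_table <- function(mat, term_matrix, models) {
  if (inherits(mat, "quant_matrix")) mat <- mat$values
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  if (!identical(colnames(mat), rownames(term_matrix)))
    term_matrix <- term_matrix[colnames(mat), , drop = FALSE]
  n <- ncol(mat)
  Yt <- t(mat)                               # workers x peptides
  tss <- colSums(sweep(Yt, 2, colMeans(Yt))^2)
  nm <- nrow(models)
  aicc <- adj <- matrix(NA_real_, nrow(mat), nm,
                        dimnames = list(rownames(mat), models$model_id))
  for (j in seq_len(nm)) {
    preds <- models$predictors[[j]]
    Xi <- cbind(1, term_matrix[, preds, drop = FALSE])
    qr_ <- qr(Xi)
    if (qr_$rank < ncol(Xi)) stop("rank-deficient model: ",
                                  models$model_id[j])
    k_coef <- length(preds)
    k <- k_coef + 2L
    if (n <= k + 1) stop("too few workers for model ", models$model_id[j])
    rss <- colSums(qr.resid(qr_, Yt)^2)
    rss[rss < 0] <- 0
    a <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    a[rss <= 1e-12 * pmax(tss, .Machine$double.eps)] <- -Inf
    aicc[, j] <- a
    adj[, j] <- ifelse(tss == 0, 0,
                       1 - (rss / (n - k_coef - 1)) / (tss / (n - 1)))
  }
  list(aicc = aicc, adj_r2 = adj)
}

#' Tabulate per-model lowest-AICc peptide votes
#'
#' For each peptide the winning model(s) are those within `delta` AICc
#' units of that peptide's minimum. At `delta = 0` each peptide casts one
#' vote, split equally among exactly tied winners (deterministic,
#' peptide-order invariant, and summing to the peptide count); at
#' `delta > 0` every co-winner counts fully, so counts may overlap
#' (sum above the peptide count, as in published per-model counts whose
#' total exceeds the screened set). Per-model
#' counts are tested against "random" with a one-sample z-test whose null
#' mean and (sample) standard deviation come from the counts across all
#' models, and corrected by Benjamini-Hochberg over a family of `m_family`
#' models.
#'
#' @param aicc features x models AICc matrix (from [aicc_table()]).
#' @param delta AICc tolerance for co-winners (default 0).
#' @param m_family BH family size (default: number of models).
#' @return data.frame `model_id`, `count`, `z`, `p` (one-sided upper),
#'   `q`, sorted by decreasing count.
#' @export
vote_models <- function(aicc, delta = 0, m_family = ncol(aicc)) {
  if (ncol(aicc) < 3) stop("z-test needs at least 3 models")
  mins <- apply(aicc, 1, min)
  winners <- aicc <= mins + delta
  count <- if (delta == 0) {
    colSums(winners / rowSums(winners))       # split exact ties equally
  } else {
    colSums(winners)                          # co-winners count fully
  }
  mu <- mean(count); s <- stats::sd(count)
  if (s == 0) {
    z <- rep(0, length(count)); p <- rep(0.5, length(count))
  } else {
    z <- (count - mu) / s
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  out <- data.frame(model_id = colnames(aicc), count = count, z = z, p = p,
                    q = bh_adjust(p, m = max(m_family, length(p))),
                    stringsAsFactors = FALSE)
  out[order(-out$count), ]
}

#' Correlation-tiered peptide sets with intersection
#'
#' Classifies peptides by adjusted R2 against each selected model into
#' moderate (`>= 0.4`) and strong (`>= 0.7`) tiers and intersects the
#' strong sets across models: the "common" peptides that stay strongly
#' exposure-correlated under every selected variable combination, guarding
#' against covariates artificially inflating R2.
#'
#' @param adj_r2 features x models adjusted-R2 matrix restricted to the
#'   selected models (columns of [aicc_table()]`$adj_r2`).
#' @param thresholds named vector `c(moderate = 0.4, strong = 0.7)`.
#' @return list with `moderate` and `strong` (lists of feature-id vectors
#'   per model), `common` (intersection of the strong sets) and `counts`.
#' @export
correlation_filter <- function(adj_r2,
                               thresholds = c(moderate = 0.4, strong = 0.7)) {
  ids <- rownames(adj_r2)
  tier <- function(th) {
    stats::setNames(lapply(seq_len(ncol(adj_r2)),
                           function(j) ids[adj_r2[, j] >= th]),
                    colnames(adj_r2))
  }
  moderate <- tier(thresholds[["moderate"]])
  strong <- tier(thresholds[["strong"]])
  common <- Reduce(intersect, strong)
  list(moderate = moderate, strong = strong, common = common,
       counts = data.frame(model_id = colnames(adj_r2),
                           moderate = lengths(moderate),
                           strong = lengths(strong),
                           stringsAsFactors = FALSE))
}
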