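# Independent oracles and fixture builders used across the suite.

# Exhaustive clustering oracle: connected components of the "all pairwise
# tolerance checks pass" graph (single linkage within tolerance). The
# greedy aligner must agree with this on well-separated instances.
brute_force_clusters <- function(events, tol) {
  n <- nrow(events)
  linked <- function(i, j) {
    ppm <- abs(events$mh_plus[i] - events$mh_plus[j]) /
      pmin(events$mh_plus[i], events$mh_plus[j]) * 1e6
    ppm <= tol$mass_tol_ppm &
      abs(events$rt[i] - events$rt[j]) <= tol$rt_tol &
      abs(events$drift_bin[i] - events$drift_bin[j]) <= tol$drift_tol
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (linked(i, j) && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Random ion events whose true clusters sit on a coarse grid separated by
# far more than twice every tolerance; within-cluster jitter stays below
# 0.4x each tolerance so all pairwise links hold inside a cluster.
make_separated_events <- function(n_clusters, n_samples = 4, seed = 1,
                                  tol = alignment_tolerances()) {
  set.seed(seed)
  centers <- data.frame(
    mh = 800 + 40 * seq_len(n_clusters),        # ~50,000 ppm apart
    rt = 5 * seq_len(n_clusters) %% 60,
    drift = 20 * seq_len(n_clusters) %% 200)
  ev <- do.call(rbind, lapply(seq_len(n_clusters), function(k) {
    ns <- sample(seq_len(n_samples), 1)
    sm <- sample(sprintf("S%02d", seq_len(n_samples)), ns)
    data.frame(
      sample_id = sm,
      mh_plus = centers$mh[k] *
        (1 + runif(ns, -0.4, 0.4) * tol$mass_tol_ppm * 1e-6),
      rt = centers$rt[k] + runif(ns, -0.4, 0.4) * tol$rt_tol,
      drift_bin = centers$drift[k] +
        sample(seq(-floor(tol$drift_tol * 0.4), floor(tol$drift_tol * 0.4)),
               ns, replace = TRUE),
      intensity = exp(runif(ns, 2, 10)),
      true_cluster = k, stringsAsFactors = FALSE)
  }))
  ev[sample(nrow(ev)), ]
}

# Likelihood-based AIC oracle via stats::lm/logLik with the additive
# normal-likelihood constants (n log 2pi + n) removed.
aic_lm_oracle <- function(y, X) {
  df <- data.frame(y = y, X)
  fit <- lm(y ~ ., data = df)
  k <- length(coef(fit)) + 1                 # + residual variance
  n <- length(y)
  aic <- -2 * as.numeric(logLik(fit)) + 2 * k - n * log(2 * pi) - n
  list(aic = aic, aicc = aic + 2 * k * (k + 1) / (n - k - 1),
       adj_r2 = summary(fit)$adj.r.squared)
}

# Small default-condition synthetic dataset shared by slower tests.
small_synth <- function(seed = 1, n_features = 2000, n_responsive = 300,
                        n_top = 41, n_nuisance = 50, ...) {
  cohort <- generate_cohort(cohort_config(seed = seed))
  pep <- generate_peptidome(
    cohort,
    peptidome_config(n_features = n_features, n_responsive = n_responsive,
                     n_top_discriminant = n_top, n_nuisance = n_nuisance,
                     seed = seed + 1000, ...))
  groups <- setNames(as.character(cohort$group), cohort$worker_id)
  list(cohort = cohort, pep = pep, groups = groups)
}
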