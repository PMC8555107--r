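#' Configuration of a synthetic worker cohort
#'
#' Parameterizes a stratified High/Low occupational CNT/F exposure cohort.
#' Breathing-zone exposure metrics (inhalable elemental carbon, respirable
#' elemental carbon, CNT/F structure counts) are lognormal, with location
#' and scale moment-matched to the arithmetic group means and standard
#' errors reported for the study population (n = 12 per group):
#'
#' \tabular{lll}{
#'   metric \tab High mean (SE) \tab Low mean (SE) \cr
#'   inhalable EC, ug/m3 \tab 8.706 (5.402) \tab 0.055 (0.014) \cr
#'   respirable EC, ug/m3 \tab 1.564 (0.964) \tab 0.017 (0.006) \cr
#'   structure count, s/cm3 \tab 0.442 (0.310) \tab 0.005 (0.002)
#' }
#'
#' Group membership is defined on inhalable EC: High workers exceed
#' `high_threshold` (0.5 ug/m3), Low workers fall below the exposure
#' `exposure_loq` (0.13 ug/m3, the inhalable EC limit of quantification);
#' draws are rejected until the constraint holds. Demographics, health
#' history, solvent exposure and the five serum cumulative inflammatory
#' potential (SCIP) covariates are drawn balanced between groups from the
#' same reported per-group summaries.
#'
#' @param n_per_group workers per group (default 12, >= 2).
#' @param high_threshold inhalable EC lower bound for High workers, ug/m3.
#' @param exposure_loq inhalable EC upper bound for Low workers, ug/m3
#'   (must be `< high_threshold`).
#' @param metric_moments data.frame overriding the per-group arithmetic
#'   mean/SE of each exposure metric; columns `metric`, `group`, `mean`,
#'   `se`, with `se` the standard error of a mean of `se_n` workers.
#' @param se_n group size the tabulated standard errors refer to.
#' @param seed integer seed; all draws are deterministic given it.
#' @return object of class `cohort_config` (a list of the above).
#' @export
cohort_config <- function(n_per_group = 12, high_threshold = 0.5,
                          exposure_loq = 0.13, metric_moments = NULL,
                          se_n = 12, seed = 20211028) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (exposure_loq >= high_threshold)
    stop("exposure_loq must be < high_threshold")
  if (is.null(metric_moments)) {
    metric_moments <- data.frame(
      metric = rep(c("inh_ec", "res_ec", "struct_count"), each = 2),
      group  = rep(c("High", "Low"), 3),
      mean   = c(8.706, 0.055, 1.564, 0.017, 0.442, 0.005),
      se     = c(5.402, 0.014, 0.964, 0.006, 0.310, 0.002),
      stringsAsFactors = FALSE)
  }
  if (any(metric_moments$mean <= 0) || any(metric_moments$se <= 0))
    stop("metric moments must be strictly positive")
  structure(list(n_per_group = n_per_group, high_threshold = high_threshold,
                 exposure_loq = exposure_loq, metric_moments = metric_moments,
                 se_n = se_n, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Moment-matched lognormal sampler
#'
#' Draws from the lognormal distribution whose arithmetic mean and standard
#' deviation equal `mean` and `sd`: with cv = sd/mean,
#' `sigma^2 = log(1 + cv^2)` and `mu = log(mean) - sigma^2 / 2`.
#'
#' @param n number of draws.
#' @param mean,sd target arithmetic mean and standard deviation (> 0).
#' @return numeric vector of positive draws.
#' @export
rlnorm_matched <- function(n, mean, sd) {
  if (mean <= 0 || sd <= 0) stop("mean and sd must be positive")
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# lognormal draws rejected until all fall inside (lower, upper)
rlnorm_bounded <- function(n, mean, sd, lower = 0, upper = Inf) {
  out <- numeric(0)
  for (i in 1:1000) {
    x <- rlnorm_matched(n - length(out), mean, sd)
    out <- c(out, x[x > lower & x < upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("rejection sampling failed; bounds incompatible with moments")
}

#' Generate a synthetic worker cohort
#'
#' Returns one exposure record per worker: group label, the three
#' breathing-zone metrics, binned demographics, health/solvent history
#' flags, and the five SCIP log fold-change covariates. Covariates are
#' drawn from the per-group summaries of the study population, hence
#' balanced between groups in expectation.
#'
#' @param config a [cohort_config()].
#' @param seed optional override of `config$seed`.
#' @return data.frame with one row per worker (`2 * n_per_group` rows):
#'   `worker_id`, `group` (factor High/Low), `inh_ec`, `res_ec`,
#'   `struct_count`, `duration_bin`, `age_bin`, `sex`, `education_bin`,
#'   `former_smoker`, `allergies`, `hypertension`, `solvent_current`,
#'   `solvent_past`, `scip_IL6`, `scip_CCL2`, `scip_TNFalpha`, `scip_VCAM`,
#'   `scip_ICAM`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_per_group
  mm <- config$metric_moments
  sd_of <- function(metric, group) {
    r <- mm[mm$metric == metric & mm$group == group, ]
    c(mean = r$mean, sd = r$se * sqrt(config$se_n))
  }
  draw_metric <- function(metric, group, lower = 0, upper = Inf) {
    m <- sd_of(metric, group)
    rlnorm_bounded(n, m["mean"], m["sd"], lower, upper)
  }
  # group membership is defined on inhalable EC; other metrics unconstrained
  one_group <- function(group) {
    inh <- if (group == "High")
      draw_metric("inh_ec", "High", lower = config$high_threshold)
    else
      draw_metric("inh_ec", "Low", upper = config$exposure_loq)
    data.frame(
      group = group,
      inh_ec = inh,
      res_ec = draw_metric("res_ec", group),
      struct_count = draw_metric("struct_count", group),
      stringsAsFactors = FALSE)
  }
  rec <- rbind(one_group("High"), one_group("Low"))
  N <- nrow(rec)
  clamp_bin <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))
  # Table-matched per-group covariate summaries (High first, Low second)
  bin_draw <- function(mean_hl, sd_hl, lo, hi) {
    mu <- rep(mean_hl, each = n); s <- rep(sd_hl, each = n)
    clamp_bin(stats::rnorm(N, mu, s * sqrt(config$se_n)), lo, hi)
  }
  flag_draw <- function(p_hl) stats::runif(N) < rep(p_hl, each = n)
  scip_draw <- function(mean_hl, se_hl)
    stats::rnorm(N, rep(mean_hl, each = n),
                 rep(se_hl, each = n) * sqrt(config$se_n))
  rec$duration_bin  <- bin_draw(c(3.3, 2.4), c(0.3, 0.4), 1, 5)
  rec$age_bin       <- bin_draw(c(3.0, 3.0), c(0.4, 0.3), 1, 5)
  rec$sex           <- factor(ifelse(flag_draw(c(0.25, 0.17)), "F", "M"))
  rec$education_bin <- bin_draw(c(2.8, 3.2), c(0.4, 0.3), 1, 4)
  rec$former_smoker   <- flag_draw(c(0.25, 0.17))
  rec$allergies       <- flag_draw(c(0.42, 0.42))
  rec$hypertension    <- flag_draw(c(0.25, 0.17))
  rec$solvent_current <- flag_draw(c(0.58, 0.50))
  rec$solvent_past    <- flag_draw(c(0.50, 0.42))
  rec$scip_IL6      <- scip_draw(c(0.958, 0.980), c(0.094, 0.069))
  rec$scip_CCL2     <- scip_draw(c(0.830, 1.001), c(0.077, 0.099))
  rec$scip_TNFalpha <- scip_draw(c(1.231, 0.950), c(0.187, 0.102))
  rec$scip_VCAM     <- scip_draw(c(1.159, 1.154), c(0.178, 0.141))
  rec$scip_ICAM     <- scip_draw(c(0.907, 1.228), c(0.128, 0.247))
  rec <- cbind(worker_id = sprintf("%s_%02d", substr(rec$group, 1, 1),
                                   c(seq_len(n), seq_len(n))),
               rec, stringsAsFactors = FALSE)
  rec$group <- factor(rec$group, levels = c("High", "Low"))
  rownames(rec) <- rec$worker_id
  rec
}

#' Configuration of a synthetic peptidome
#'
#' Parameterizes the peptide feature matrix layered on a cohort. Features
#' fall into four planted classes with ground truth emitted alongside:
#' \describe{
#'   \item{null}{baseline intensity plus noise; no association with any
#'     worker variable. Used for type-I error control checks.}
#'   \item{responsive}{log2 intensity linear in the worker composite
#'     exposure (the equal-weight sum of log10 exposure metrics), with the
#'     noise variance solved from `var(beta * x) * (1 - r2) / r2` so the
#'     expected coefficient of determination against the composite equals
#'     `target_r2`.}
#'   \item{top_discriminant}{group-shifted peptides whose High-minus-Low
#'     mean difference is drawn uniformly from `top_effect_log2_range`
#'     (default 10-13 log2 units, i.e. 3-4 orders of magnitude).}
#'   \item{nuisance}{peptides linear in a non-exposure covariate (serum IL6
#'     induction or age bin), planted to exercise the correlation-filter
#'     intersection logic.}
#' }
#' Cells whose latent raw intensity falls below `2^log2_loq` are recorded
#' missing (hard left-censoring at the intensity limit of quantification);
#' an optional missing-completely-at-random mode supports null testing.
#'
#' @param n_features total peptide features (default 12,000).
#' @param n_responsive composite-linear peptides (default 900).
#' @param n_top_discriminant group-shifted peptides (default 41); counted
#'   within `n_responsive`? No: classes are disjoint, and
#'   `n_top_discriminant + n_responsive + n_nuisance <= n_features`.
#' @param n_nuisance covariate-linked peptides (default 150).
#' @param top_effect_log2_range interval for top-discriminant group
#'   differences, log2 units.
#' @param target_r2 expected composite R2 of responsive (and nuisance,
#'   against their covariate) peptides, in (0, 1).
#' @param noise_sd within-worker log2 noise for null and top-discriminant
#'   peptides (default 0.15 log2 units, an ~11% intensity coefficient of
#'   variation). The default emulates the high within-group consistency
#'   the study reports for its top discriminant ions (near-unity
#'   cross-validated predictive power); within-group variance of real
#'   peptides is otherwise unreported, so this is a free parameter.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-feature
#'   baseline log2 intensity.
#' @param log2_loq intensity limit of quantification, log2 units; raw LOQ
#'   is `2^log2_loq`.
#' @param low_margin_log2 offset above the LOQ of the Low-group mean of
#'   top-discriminant peptides (keeps them quantifiable in both groups).
#' @param missing_mode `"censor"` (left-censor below LOQ) or `"mcar"`.
#' @param mcar_rate cell missingness probability under `"mcar"`.
#' @param seed integer seed.
#' @return object of class `peptidome_config`.
#' @export
peptidome_config <- function(n_features = 12000, n_responsive = 900,
                             n_top_discriminant = 41, n_nuisance = 150,
                             top_effect_log2_range = c(10, 13),
                             target_r2 = 0.85, noise_sd = 0.15,
                             baseline_log2_mean = 14, baseline_log2_sd = 2,
                             log2_loq = 6, low_margin_log2 = 3,
                             missing_mode = c("censor", "mcar"),
                             mcar_rate = 0.05, seed = 20211028) {
  missing_mode <- match.arg(missing_mode)
  if (n_top_discriminant + n_responsive + n_nuisance > n_features)
    stop("planted classes exceed n_features")
  if (target_r2 <= 0 || target_r2 >= 1) stop("target_r2 must be in (0,1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(top_effect_log2_range) != 2 ||
      diff(top_effect_log2_range) < 0)
    stop("top_effect_log2_range must be an increasing interval")
  structure(list(n_features = n_features, n_responsive = n_responsive,
                 n_top_discriminant = n_top_discriminant,
                 n_nuisance = n_nuisance,
                 top_effect_log2_range = top_effect_log2_range,
                 target_r2 = target_r2, noise_sd = noise_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 log2_loq = log2_loq, low_margin_log2 = low_margin_log2,
                 missing_mode = missing_mode, mcar_rate = mcar_rate,
                 seed = as.integer(seed)),
            class = "peptidome_config")
}

# noise sd giving expected R^2 = r2 for a linear signal vector
.noise_sd_for_r2 <- function(signal, r2) {
  vs <- stats::var(signal)
  sqrt(vs * (1 - r2) / r2)
}

#' Generate a synthetic peptidome matrix with ground truth
#'
#' Lays a peptide feature matrix over a cohort (see [peptidome_config()]
#' for the planted feature classes) and applies left-censoring at the
#' intensity limit of quantification. The returned ground-truth table makes
#' recovery metrics (sensitivity, FDR, VIP recall) computable.
#'
#' @param cohort data.frame from [generate_cohort()]; must contain both
#'   exposure groups.
#' @param config a [peptidome_config()].
#' @param seed optional override of `config$seed`.
#' @return list with elements:
#'   \describe{
#'     \item{matrix}{a raw-scale [quant_matrix()], `n_features` rows x
#'       workers, `NA` where censored.}
#'     \item{truth}{data.frame `feature_id`, `class`, `beta` (composite
#'       slope, group shift, or covariate slope per class), `target`
#'       (the worker variable the peptide tracks), `alpha`, `noise_sd`.}
#'     \item{composite}{the per-worker composite exposure used for
#'       responsive peptides.}
#'   }
#' @export
generate_peptidome <- function(cohort, config = peptidome_config(),
                               seed = config$seed) {
  stopifnot(inherits(config, "peptidome_config"))
  if (!all(c("High", "Low") %in% cohort$group))
    stop("cohort must contain both exposure groups")
  set.seed(seed)
  N <- nrow(cohort)
  P <- config$n_features
  x <- make_composite(cohort)            # log-sum exposure per worker
  xc <- x - mean(x)
  high <- cohort$group == "High"

  classes <- rep("null", P)
  idx_top  <- seq_len(config$n_top_discriminant)
  idx_resp <- seq_len(config$n_responsive) + config$n_top_discriminant
  idx_nui  <- seq_len(config$n_nuisance) +
    config$n_top_discriminant + config$n_responsive
  classes[idx_top] <- "top_discriminant"
  classes[idx_resp] <- "responsive"
  classes[idx_nui] <- "nuisance"

  alpha <- stats::rnorm(P, config$baseline_log2_mean, config$baseline_log2_sd)
  beta <- rep(0, P)
  nsd <- rep(config$noise_sd, P)
  target <- rep("none", P)
  log2m <- matrix(alpha, P, N) # each column starts at the feature baseline

  # top-discriminant: group shift of 10-13 log2 units, increased or
  # decreased in High with equal probability (serum peptides respond in
  # both directions); the less abundant group's mean is pinned just above
  # the LOQ so both groups stay quantifiable, and balanced signs keep the
  # column medians free of a group-level normalization bias
  if (length(idx_top)) {
    eff <- stats::runif(length(idx_top), config$top_effect_log2_range[1],
                        config$top_effect_log2_range[2]) *
      sample(c(-1, 1), length(idx_top), replace = TRUE)
    alpha[idx_top] <- config$log2_loq + config$low_margin_log2 +
      pmax(0, -eff)
    beta[idx_top] <- eff
    target[idx_top] <- "group"
    log2m[idx_top, ] <- alpha[idx_top] +
      outer(eff, as.numeric(high))
  }
  # responsive: linear in composite exposure (slope sign random), noise
  # solved for target_r2
  if (length(idx_resp)) {
    dx <- mean(x[high]) - mean(x[!high])
    eff <- stats::runif(length(idx_resp), 1, 4) *    # 2- to 16-fold shifts
      sample(c(-1, 1), length(idx_resp), replace = TRUE)
    b <- eff / dx
    beta[idx_resp] <- b
    nsd[idx_resp] <- vapply(b, function(bi)
      .noise_sd_for_r2(bi * xc, config$target_r2), numeric(1))
    target[idx_resp] <- "composite"
    log2m[idx_resp, ] <- alpha[idx_resp] + outer(b, xc)
  }
  # nuisance: linear in a non-exposure covariate, same r2 calibration
  if (length(idx_nui)) {
    covs <- cbind(IL6 = cohort$scip_IL6, age = as.numeric(cohort$age_bin))
    which_cov <- sample(colnames(covs), length(idx_nui), replace = TRUE)
    eff <- stats::runif(length(idx_nui), 1, 4) *
      sample(c(-1, 1), length(idx_nui), replace = TRUE)
    for (j in seq_along(idx_nui)) {
      z <- covs[, which_cov[j]]
      zc <- z - mean(z)
      sz <- stats::sd(z)
      if (sz == 0) next
      b <- eff[j] / (2 * sz)
      beta[idx_nui[j]] <- b
      nsd[idx_nui[j]] <- .noise_sd_for_r2(b * zc, config$target_r2)
      log2m[idx_nui[j], ] <- alpha[idx_nui[j]] + b * zc
    }
    target[idx_nui] <- paste0("scip_", sub("age", "", which_cov))
    target[idx_nui][which_cov == "age"] <- "age_bin"
  }
  log2m <- log2m + matrix(stats::rnorm(P * N, 0, rep(nsd, N)), P, N)

  raw <- 2^log2m
  dimnames(raw) <- list(sprintf("pep_%05d", seq_len(P)), cohort$worker_id)
  loq <- 2^config$log2_loq
  if (config$missing_mode == "censor") {
    raw[raw < loq] <- NA
  } else {
    raw[matrix(stats::runif(P * N) < config$mcar_rate, P, N)] <- NA
  }
  truth <- data.frame(feature_id = rownames(raw), class = classes,
                      beta = beta, target = target, alpha = alpha,
                      noise_sd = nsd, stringsAsFactors = FALSE)
  list(matrix = quant_matrix(raw, intensity_loq = loq),
       truth = truth,
       composite = stats::setNames(x, cohort$worker_id))
}

#' Write / read worker records as TSV
#' @param cohort data.frame from [generate_cohort()].
#' @param path TSV path.
#' @export
write_workers <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_workers
#' @export
read_workers <- function(path) {
  w <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  w$group <- factor(w$group, levels = c("High", "Low"))
  if (!is.null(w$sex)) w$sex <- factor(w$sex)
  rownames(w) <- w$worker_id
  w
}
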