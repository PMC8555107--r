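#' Pipeline configuration
#'
#' Assembles the end-to-end run configuration. Input is either synthetic
#' (cohort + peptidome generator configs) or a pair of TSV paths (worker
#' table and quant matrix, or per-sample ion-event lists to be aligned).
#' All stage randomness derives from the single root `seed`.
#'
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param peptidome a [peptidome_config()] (synthetic mode).
#' @param workers_tsv,matrix_tsv,events input paths (file mode); `events`
#'   is a directory or vector of per-sample ion-event TSVs, aligned with
#'   `tolerances` in place of `matrix_tsv`.
#' @param tolerances an [alignment_tolerances()].
#' @param min_frac_reproducible,min_frac_powered the two detection-filter
#'   tiers (defaults 0.5 and 0.75).
#' @param fdr univariate screen false discovery rate (default 0.05).
#' @param vote_q model-vote significance threshold (default 0.05).
#' @param m_family BH family size for the vote test (default: enumerated
#'   model count).
#' @param models model space data.frame (default [enumerate_models()]).
#' @param thresholds correlation tiers (`moderate`, `strong`).
#' @param vip_cutoff,top_k discriminant selection (defaults 1.0 and 5).
#' @param n_components PLS components.
#' @param cv_scheme,cv_repeats,cv_holdout cross-validation settings.
#' @param seed root seed; per-stage seeds are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            peptidome = peptidome_config(),
                            workers_tsv = NULL, matrix_tsv = NULL,
                            events = NULL,
                            tolerances = alignment_tolerances(),
                            min_frac_reproducible = 0.5,
                            min_frac_powered = 0.75,
                            fdr = 0.05, vote_q = 0.05, m_family = NULL,
                            models = enumerate_models(),
                            thresholds = c(moderate = 0.4, strong = 0.7),
                            vip_cutoff = 1.0, top_k = 5, n_components = 2,
                            cv_scheme = "monte_carlo", cv_repeats = 50,
                            cv_holdout = 4, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

# per-stage seeds derived from one root seed (kept below 2^31; double
# arithmetic avoids 32-bit overflow before the modulus)
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %%
               2147483629)
}

#' Run the full biomarker discovery pipeline
#'
#' Executes, in order: simulate/ingest -> (align) -> preprocess ->
#' univariate screen -> model voting -> correlation filter -> PLS-DA / VIP
#' ranking -> cross-validation, split-sample validation and unsupervised
#' PCA. Returns all stage outputs plus a machine-readable run manifest
#' whose filtering-chain counts are monotone non-increasing. With
#' `out_dir` set, stage tables (TSV) and the manifest (JSON) are written.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `manifest` and stage outputs (`cohort`, `matrix_raw`,
#'   `matrix_processed`, `screen`, `votes`, `correlation`, `vip`, `top`,
#'   `cv`, `validation`, `pca`, `truth` when synthetic).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- "input"
  res <- list()
  manifest <- list(seed = config$seed,
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  abort <- function(msg) stop(sprintf("pipeline stage '%s': %s", stage, msg),
                              call. = FALSE)
  # -- simulate or ingest ----------------------------------------------
  if (!is.null(config$workers_tsv)) {
    cohort <- read_workers(config$workers_tsv)
    truth <- NULL
    if (!is.null(config$events)) {
      stage <- "align"
      events <- read_ion_events(config$events)
      qm <- cluster_ion_events(events, config$tolerances)
    } else if (!is.null(config$matrix_tsv)) {
      qm <- read_quant_matrix(config$matrix_tsv)
    } else abort("file mode needs matrix_tsv or events")
  } else {
    stage <- "simulate"
    cohort <- generate_cohort(config$cohort,
                              seed = .stage_seed(config$seed, 1L))
    pg <- generate_peptidome(cohort, config$peptidome,
                             seed = .stage_seed(config$seed, 2L))
    qm <- pg$matrix
    truth <- pg$truth
  }
  groups <- stats::setNames(as.character(cohort$group), cohort$worker_id)
  res$cohort <- cohort; res$truth <- truth; res$matrix_raw <- qm
  manifest$n_workers <- ncol(qm$values)
  manifest$n_features_aligned <- nrow(qm$values)

  # -- preprocessing ----------------------------------------------------
  stage <- "preprocess"
  qm50 <- filter_by_detection(qm, groups, config$min_frac_reproducible)
  manifest$n_detect_reproducible <- nrow(qm50$values)
  qm75 <- filter_by_detection(qm50, groups, config$min_frac_powered)
  manifest$n_detect_powered <- nrow(qm75$values)
  if (nrow(qm75$values) == 0) abort("no peptides pass the detection filters")
  proc <- log2_and_standardize(
    impute_left_censored(median_center(qm75)), groups)
  res$matrix_processed <- proc
  manifest$power_two_fold <- power_two_group(
    min(table(cohort$group)), effect_log2 = 1,
    sd_log2 = median_pooled_sd(proc$values, groups[workers(proc)]))

  # -- univariate screen ------------------------------------------------
  stage <- "univariate"
  screen <- row_t_test(proc$values, groups[workers(proc)])
  sig_ids <- screen$feature_id[screen$q < config$fdr]
  res$screen <- screen
  manifest$n_significant <- length(sig_ids)
  if (length(sig_ids) == 0) {
    manifest$n_moderate <- manifest$n_strong <- manifest$n_common <- 0L
    manifest$n_vip <- manifest$n_top <- 0L
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    res$manifest <- manifest
    if (!is.null(out_dir)) .write_outputs(res, config, out_dir)
    return(res)
  }
  sig <- proc$values[sig_ids, , drop = FALSE]

  # -- model voting -----------------------------------------------------
  stage <- "model_build"
  tm <- model_terms(cohort)
  # models whose design is not full rank for this cohort (e.g. a history
  # flag constant across workers) are not estimable and sit out the vote
  estimable <- vapply(config$models$predictors, function(preds) {
    Xi <- cbind(1, tm[, preds, drop = FALSE])
    qr(Xi)$rank == ncol(Xi)
  }, logical(1))
  models_use <- config$models[estimable, , drop = FALSE]
  manifest$n_models_dropped <- sum(!estimable)
  if (nrow(models_use) < 3) abort("fewer than 3 estimable models")
  scores <- aicc_table(sig, tm, models_use)
  m_family <- config$m_family %||% nrow(config$models)
  votes <- vote_models(scores$aicc, m_family = m_family)
  sig_models <- votes$model_id[votes$q < config$vote_q]
  if (!length(sig_models)) sig_models <- votes$model_id[1]
  res$votes <- votes
  manifest$n_models <- nrow(config$models)
  manifest$significant_models <- sig_models

  # -- correlation filter ----------------------------------------------
  # the common set intersects the best-voted model with its significant
  # covariate extensions (nested supersets), not with non-nested rivals:
  # covariates can only be checked against the winning exposure construct
  stage <- "correlation"
  best <- votes$model_id[1]
  best_preds <- models_use$predictors[[match(best, models_use$model_id)]]
  nested <- vapply(sig_models, function(mid) {
    preds <- models_use$predictors[[match(mid, models_use$model_id)]]
    all(best_preds %in% preds)
  }, logical(1))
  corr_models <- unique(c(best, sig_models[nested]))
  manifest$correlation_models <- corr_models
  corr <- correlation_filter(
    scores$adj_r2[, corr_models, drop = FALSE], config$thresholds)
  res$correlation <- corr
  manifest$n_moderate <- max(corr$counts$moderate)
  manifest$n_strong <- max(corr$counts$strong)
  manifest$n_common <- length(corr$common)
  if (!length(corr$common)) abort("no strongly correlated common peptides")

  # -- discriminant model ----------------------------------------------
  stage <- "discriminate"
  Xw <- t(proc$values[corr$common, , drop = FALSE])
  yw <- factor(groups[rownames(Xw)], levels = c("High", "Low"))
  fit <- fit_plsda(Xw, yw, n_components = config$n_components)
  vips <- vip_scores(fit)
  selected <- select_discriminant(vips, config$vip_cutoff)
  top <- select_discriminant(vips, config$vip_cutoff, config$top_k)
  res$plsda <- fit; res$vip <- vips
  res$selected <- selected; res$top <- top
  manifest$n_vip <- nrow(selected)
  manifest$n_top <- nrow(top)
  manifest$top_peptides <- top$feature_id
  if (nrow(top) == 0) abort("no peptides reach the VIP cutoff")

  # -- validation -------------------------------------------------------
  stage <- "validate"
  res$cv <- cross_validate(Xw, yw, features = top$feature_id,
                           scheme = config$cv_scheme,
                           n_repeats = config$cv_repeats,
                           holdout = config$cv_holdout,
                           n_components = config$n_components,
                           seed = .stage_seed(config$seed, 3L))
  res$validation <- validate_split(Xw, yw, features = top$feature_id,
                                   n_repeats = config$cv_repeats,
                                   n_components = config$n_components,
                                   seed = .stage_seed(config$seed, 4L))
  res$pca <- pca_variance(t(proc$values))
  manifest$cv <- list(scheme = res$cv$scheme, accuracy = res$cv$accuracy,
                      r2 = res$cv$r2, q2 = res$cv$q2)
  manifest$validation_accuracy <- res$validation$accuracy
  manifest$pca_fraction_pc1 <- res$pca$fractions[1]
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  res$manifest <- manifest
  if (!is.null(out_dir)) .write_outputs(res, config, out_dir)
  res
}

.write_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_workers(res$cohort, fp("workers.tsv"))
  write_quant_matrix(res$matrix_raw, fp("quant_matrix.tsv"))
  if (!is.null(res$truth))
    utils::write.table(res$truth, fp("ground_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$matrix_processed))
    write_quant_matrix(res$matrix_processed, fp("processed_matrix.tsv"))
  if (!is.null(res$screen))
    utils::write.table(res$screen, fp("univariate_screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$votes))
    utils::write.table(res$votes, fp("model_votes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$vip))
    utils::write.table(res$vip, fp("vip_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$correlation))
    writeLines(res$correlation$common, fp("strong_common_peptides.tsv"))
  if (!is.null(res$validation))
    utils::write.table(res$validation$class_probabilities,
                       fp("class_probabilities.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$pca))
    utils::write.table(
      data.frame(component = seq_along(res$pca$fractions),
                 fraction = res$pca$fractions),
      fp("pca_variance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- res$manifest
  manifest$config_hash <- config_hash(config)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Hash of a pipeline configuration
#'
#' MD5 digest of the serialized configuration (model predictor lists
#' flattened), recorded in the run manifest for provenance.
#'
#' @param config a [pipeline_config()].
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  canon <- config
  canon$models <- paste(canon$models$model_id, collapse = ";")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(canon, digits.d = 16)), tmp)
  unname(tools::md5sum(tmp))
}
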