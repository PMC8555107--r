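#' Filter peptides by per-group detection fraction
#'
#' Reproducibility filter: keeps peptides detected in at least `min_frac`
#' of workers per group. The default `"both"` rule requires the fraction in
#' each group (e.g. at least 9 of 12 workers per group at `min_frac =
#' 0.75`); `"either"` accepts one qualifying group.
#'
#' @param x a raw-scale [quant_matrix()].
#' @param groups named worker-to-group mapping (see [detection_counts()]).
#' @param min_frac minimum detection fraction, in (0, 1].
#' @param rule `"both"` (default) or `"either"`.
#' @return filtered [quant_matrix()], row order preserved. An empty result
#'   is allowed (with a warning).
#' @export
filter_by_detection <- function(x, groups, min_frac = 0.75,
                                rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  frac <- detection_counts(x, groups)
  keep <- if (rule == "both") apply(frac >= min_frac, 1, all)
          else apply(frac >= min_frac, 1, any)
  if (!any(keep)) warning("no peptides pass the detection filter")
  subset_quant(x, keep)
}

# row subset preserving metadata and imputation mask
subset_quant <- function(x, keep) {
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out$features <- x$features[keep, , drop = FALSE]
  out$imputed <- x$imputed[keep, , drop = FALSE]
  out
}

#' Median center sample columns
#'
#' Rescales each sample (column) multiplicatively so all observed column
#' medians agree. The common target is the log-space median of the column
#' medians (the geometric mean of the two middle medians for even column
#' counts), making the operation an additive median centering in log2 space
#' while preserving the positivity needed for the later log2 transform.
#'
#' @param x a raw-scale [quant_matrix()] (missing cells untouched).
#' @return centered [quant_matrix()].
#' @export
median_center <- function(x) {
  if (x$scale != "raw") stop("median centering applies to raw intensities")
  med <- apply(x$values, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med)))
    stop("column with no observed values cannot be centered")
  target <- 2^stats::median(log2(med))
  out <- x
  out$values <- sweep(x$values, 2, target / med, `*`)
  out
}

#' Impute left-censored cells at the limit of quantification
#'
#' Missing cells arise from non-random left-censoring (ion intensities
#' below the limit of quantification are undetected), so they are imputed
#' at the intensity LOQ itself. Observed values are never modified and the
#' provenance of imputed cells is retained in the `imputed` mask.
#'
#' @param x a raw-scale [quant_matrix()] with `intensity_loq` set.
#' @param loq override of `x$intensity_loq`.
#' @return imputed [quant_matrix()] with no missing cells.
#' @export
impute_left_censored <- function(x, loq = x$intensity_loq) {
  if (is.null(loq) || is.na(loq)) stop("intensity LOQ is not set")
  out <- x
  miss <- is.na(x$values)
  out$values[miss] <- loq
  out$imputed <- out$imputed | miss
  out$intensity_loq <- loq
  out
}

#' Log2 transform and standardize to the Low-group mean
#'
#' Converts intensities to log2 and expresses every peptide as its log2
#' fold difference from the mean of the reference (Low exposure) group, so
#' a value of +10 is a 2^10-fold elevation over the Low-group mean. After
#' standardization the reference-group mean of every peptide is zero and
#' the matrix scale flag becomes `"log2_fold_from_low"`.
#'
#' @param x a raw-scale [quant_matrix()] with strictly positive values
#'   (run after [impute_left_censored()]).
#' @param groups named worker-to-group mapping.
#' @param reference reference group label (default `"Low"`).
#' @return standardized [quant_matrix()].
#' @export
log2_and_standardize <- function(x, groups, reference = "Low") {
  if (x$scale != "raw") stop("matrix is already standardized")
  if (anyNA(x$values)) stop("impute missing cells before log2 transform")
  if (any(x$values <= 0)) stop("log2 requires strictly positive intensities")
  w <- workers(x)
  if (is.null(names(groups))) names(groups) <- w
  ref_cols <- w[groups[w] == reference]
  if (!length(ref_cols)) stop("reference group has no workers")
  lv <- log2(x$values)
  out <- x
  out$values <- lv - rowMeans(lv[, ref_cols, drop = FALSE])
  out$scale <- "log2_fold_from_low"
  out
}

#' Full quantitative preprocessing chain
#'
#' Convenience wrapper running the preprocessing in its default order:
#' detection filter -> median centering -> left-censored imputation at the
#' LOQ -> log2 transform with standardization to the Low-group mean. The
#' center/impute order is switchable.
#'
#' @param x a raw-scale [quant_matrix()].
#' @param groups named worker-to-group mapping.
#' @param min_frac detection filter threshold (see [filter_by_detection()]).
#' @param rule detection filter rule.
#' @param order `"center_first"` (default) or `"impute_first"`.
#' @return standardized [quant_matrix()].
#' @export
preprocess <- function(x, groups, min_frac = 0.75, rule = "both",
                       order = c("center_first", "impute_first")) {
  order <- match.arg(order)
  x <- filter_by_detection(x, groups, min_frac, rule)
  if (order == "center_first") {
    x <- impute_left_censored(median_center(x))
  } else {
    x <- median_center(impute_left_censored(x))
  }
  log2_and_standardize(x, groups)
}
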