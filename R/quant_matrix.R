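#' Quantitative peptide-by-worker intensity matrix
#'
#' The central container of the pipeline: a numeric matrix of peptide ion
#' intensities (rows = peptide features, columns = workers) with an explicit
#' missingness convention (`NA` = not detected), an intensity limit of
#' quantification (LOQ) used for left-censored imputation, and a scale flag
#' tracking the preprocessing state (`"raw"` positive intensities or
#' `"log2_fold_from_low"` after log2 transform and standardization to the
#' Low-exposure group mean).
#'
#' @param values numeric matrix, features x workers; `NA` marks a missing
#'   (undetected) cell. Must have column names (worker ids).
#' @param features optional data.frame of per-feature metadata (one row per
#'   matrix row), e.g. cluster centroids `mh_plus`, `rt`, `drift_bin`. A
#'   `feature_id` column is created from rownames when absent.
#' @param intensity_loq minimum quantifiable intensity, in the units of
#'   `values` on the raw scale. Defaults to the smallest observed value.
#' @param scale `"raw"` or `"log2_fold_from_low"`.
#' @return An object of class `quant_matrix`: a list with elements `values`,
#'   `features`, `intensity_loq`, `scale`, and `imputed` (logical matrix
#'   marking cells filled by left-censored imputation, all `FALSE` initially).
#' @export
quant_matrix <- function(values, features = NULL, intensity_loq = NULL,
                         scale = c("raw", "log2_fold_from_low")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("`values` must carry worker ids as column names")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("pep_%05d", seq_len(nrow(values)))
  if (scale == "raw" && any(values[!is.na(values)] <= 0))
    stop("raw-scale intensities must be strictly positive")
  if (is.null(features)) {
    features <- data.frame(feature_id = rownames(values),
                           stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features)
    if (nrow(features) != nrow(values))
      stop("`features` must have one row per matrix row")
    if (is.null(features$feature_id)) features$feature_id <- rownames(values)
  }
  if (is.null(intensity_loq)) {
    obs <- values[!is.na(values)]
    intensity_loq <- if (length(obs)) min(obs) else NA_real_
  }
  structure(
    list(values = values, features = features,
         intensity_loq = intensity_loq, scale = scale,
         imputed = matrix(FALSE, nrow(values), ncol(values),
                          dimnames = dimnames(values))),
    class = "quant_matrix")
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' @export
print.quant_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("quant_matrix: %d features x %d workers [%s]\n",
              nrow(v), ncol(v), x$scale))
  cat(sprintf("  missing: %.1f%%  intensity LOQ: %s  imputed cells: %d\n",
              100 * mean(is.na(v)), format(x$intensity_loq),
              sum(x$imputed)))
  invisible(x)
}

#' @export
as.matrix.quant_matrix <- function(x, ...) x$values

#' Worker ids of a quant_matrix
#' @param x a `quant_matrix`.
#' @return character vector of column (worker) names.
#' @export
workers <- function(x) colnames(x$values)

#' Write / read a quant_matrix as TSV
#'
#' Plain-text round trip: rows are peptide features, columns are worker ids,
#' an empty cell encodes a missing value. The LOQ and scale travel in `#`
#' header comment lines so a written matrix re-reads losslessly.
#'
#' @param x a `quant_matrix`.
#' @param path file path of the TSV.
#' @export
write_quant_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# intensity_loq=%.17g", x$intensity_loq), con)
  writeLines(sprintf("# scale=%s", x$scale), con)
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_matrix
#' @export
read_quant_matrix <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key, default) {
    hit <- grep(paste0("^# *", key, "="), hdr, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^# *", key, "="), "", hit[1])
  }
  loq <- as.numeric(get_field("intensity_loq", NA))
  scl <- get_field("scale", "raw")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  quant_matrix(m, intensity_loq = loq, scale = scl)
}
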