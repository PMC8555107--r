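#' Alignment tolerances for cross-sample ion clustering
#'
#' The three-dimensional matching window used to align ion events across
#' biological replicates: chromatographic retention time (+/- 2 min),
#' ion-mobility drift time (+/- 4 bins, inclusive) and charge-reduced ion
#' mass MH+ (+/- 6 ppm).
#'
#' @param rt_tol retention-time tolerance, minutes (> 0).
#' @param drift_tol drift-time tolerance, bins (> 0, inclusive).
#' @param mass_tol_ppm mass tolerance, parts per million (> 0).
#' @return object of class `alignment_tolerances`.
#' @export
alignment_tolerances <- function(rt_tol = 2, drift_tol = 4,
                                 mass_tol_ppm = 6) {
  if (rt_tol <= 0 || drift_tol <= 0 || mass_tol_ppm <= 0)
    stop("all tolerances must be strictly positive")
  structure(list(rt_tol = rt_tol, drift_tol = drift_tol,
                 mass_tol_ppm = mass_tol_ppm),
            class = "alignment_tolerances")
}

#' Cluster per-sample ion events into cross-sample peptide features
#'
#' Greedy, intensity-seeded clustering: events are processed in descending
#' intensity; each event joins the existing cluster whose intensity-weighted
#' running centroid lies within all three tolerances (ties broken by
#' smallest mass difference), or seeds a new cluster. When one sample
#' contributes several events to a cluster their intensities are summed.
#' The mass distance is measured in ppm relative to the running centroid
#' mass; the drift window is inclusive (`|d - centroid| <= drift_tol`).
#'
#' Greedy intensity-ordered assignment is deterministic and, for clusters
#' separated by more than twice each tolerance, provably recovers the
#' exhaustive within-tolerance connected components.
#'
#' @param events data.frame with columns `sample_id`, `mh_plus` (Da, > 0),
#'   `rt` (minutes), `drift_bin` (integer), `intensity` (> 0).
#' @param tol an [alignment_tolerances()].
#' @return a raw-scale [quant_matrix()] whose features carry the cluster
#'   centroids (`mh_plus`, `rt`, `drift_bin`, `n_events`); `intensity_loq`
#'   defaults to the smallest clustered cell intensity.
#' @export
cluster_ion_events <- function(events, tol = alignment_tolerances()) {
  req <- c("sample_id", "mh_plus", "rt", "drift_bin", "intensity")
  if (!all(req %in% names(events))) stop("events need columns: ",
                                         paste(req, collapse = ", "))
  if (nrow(events) == 0) stop("no ion events supplied")
  if (any(events$intensity <= 0) || any(events$mh_plus <= 0))
    stop("intensities and masses must be strictly positive")

  ord <- order(-events$intensity, events$mh_plus)
  ev <- events[ord, ]
  n <- nrow(ev)
  # running centroids (intensity-weighted), grown as clusters appear
  cm <- numeric(n); crt <- numeric(n); cdr <- numeric(n); cw <- numeric(n)
  nclust <- 0L
  assign <- integer(n)
  for (i in seq_len(n)) {
    m <- ev$mh_plus[i]; r <- ev$rt[i]; d <- ev$drift_bin[i]
    k <- 0L
    if (nclust > 0L) {
      j <- seq_len(nclust)
      dm_ppm <- abs(m - cm[j]) / cm[j] * 1e6
      ok <- dm_ppm <= tol$mass_tol_ppm &
        abs(r - crt[j]) <= tol$rt_tol &
        abs(d - cdr[j]) <= tol$drift_tol
      if (any(ok)) k <- j[ok][which.min(dm_ppm[ok])]
    }
    w <- ev$intensity[i]
    if (k == 0L) {
      nclust <- nclust + 1L
      k <- nclust
      cm[k] <- m; crt[k] <- r; cdr[k] <- d; cw[k] <- w
    } else {
      tw <- cw[k] + w
      cm[k]  <- (cm[k] * cw[k] + m * w) / tw
      crt[k] <- (crt[k] * cw[k] + r * w) / tw
      cdr[k] <- (cdr[k] * cw[k] + d * w) / tw
      cw[k] <- tw
    }
    assign[i] <- k
  }
  samples <- sort(unique(ev$sample_id))
  vals <- matrix(NA_real_, nclust, length(samples),
                 dimnames = list(sprintf("pep_%05d", seq_len(nclust)),
                                 samples))
  agg <- tapply(ev$intensity,
                list(cluster = assign, sample = ev$sample_id), sum)
  vals[cbind(as.integer(rownames(agg)[row(agg)]),
             match(colnames(agg)[col(agg)], samples))] <- agg
  feats <- data.frame(feature_id = rownames(vals),
                      mh_plus = cm[seq_len(nclust)],
                      rt = crt[seq_len(nclust)],
                      drift_bin = cdr[seq_len(nclust)],
                      n_events = tabulate(assign, nclust),
                      stringsAsFactors = FALSE)
  quant_matrix(vals, features = feats)
}

#' Per-peptide per-group detection fractions
#'
#' Fraction of workers in each group with a quantified (non-missing) value,
#' the quantity thresholded by the reproducibility filters (>= 50% and
#' >= 75% of workers per group, i.e. at least 9 of 12).
#'
#' @param x a [quant_matrix()].
#' @param groups named vector/factor mapping every worker id to its group.
#' @return numeric matrix, features x groups, fractions in \[0, 1\].
#' @export
detection_counts <- function(x, groups) {
  w <- workers(x)
  if (is.null(names(groups))) {
    if (length(groups) != length(w))
      stop("groups must be named by worker id or match column order")
    names(groups) <- w
  }
  if (!all(w %in% names(groups))) stop("unknown worker id in matrix")
  g <- factor(groups[w])
  det <- !is.na(x$values)
  frac <- vapply(levels(g), function(lv)
    rowMeans(det[, g == lv, drop = FALSE]), numeric(nrow(det)))
  if (is.null(dim(frac)))
    frac <- matrix(frac, nrow = 1, dimnames = list(rownames(det), levels(g)))
  frac
}

#' Read / write per-sample ion-event TSV files
#'
#' Events are stored one file per sample or as a single combined table with
#' columns `sample_id`, `mh_plus`, `rt`, `drift_bin`, `intensity`.
#'
#' @param paths one or more TSV paths (a directory expands to its `.tsv`
#'   files).
#' @return combined events data.frame.
#' @export
read_ion_events <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
  do.call(rbind, lapply(paths, function(p)
    utils::read.table(p, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)))
}

#' @rdname read_ion_events
#' @param events events data.frame.
#' @param path output TSV path.
#' @export
write_ion_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
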