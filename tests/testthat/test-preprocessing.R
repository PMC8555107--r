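make_qm <- function(values, loq = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("w%02d", seq_len(ncol(values)))
  quant_matrix(values, intensity_loq = loq)
}

test_that("detection filter applies the both-group rule and is monotone", {
  m <- matrix(NA_real_, 3, 24)
  m[1, c(1:9, 13:21)] <- 10      # 75% / 75%  -> kept at 0.75
  m[2, c(1:6, 13:17)] <- 10      # 50% / 41.7% -> dropped at 0.5 (both rule)
  m[3, c(1:12, 13:18)] <- 10     # 100% / 50%
  colnames(m) <- c(sprintf("H%02d", 1:12), sprintf("L%02d", 1:12))
  rownames(m) <- c("p1", "p2", "p3")
  groups <- setNames(rep(c("High", "Low"), each = 12), colnames(m))
  qm <- make_qm(m)
  expect_equal(rownames(filter_by_detection(qm, groups, 0.75)$values), "p1")
  expect_equal(rownames(filter_by_detection(qm, groups, 0.5)$values),
               c("p1", "p3"))
  expect_equal(rownames(filter_by_detection(qm, groups, 0.5,
                                            rule = "either")$values),
               c("p1", "p2", "p3"))
  # vacuous filter keeps everything detected at least once
  expect_equal(nrow(filter_by_detection(qm, groups, 1e-9)$values), 3)
  # monotonicity: the 0.75 retained set nests inside the 0.5 set
  s <- small_synth(seed = 12, n_features = 500, n_responsive = 50,
                   n_top = 20, n_nuisance = 0)
  k75 <- rownames(filter_by_detection(s$pep$matrix, s$groups, 0.75)$values)
  k50 <- rownames(filter_by_detection(s$pep$matrix, s$groups, 0.5)$values)
  expect_true(all(k75 %in% k50))
})

test_that("median centering equalizes column medians at the log-space median", {
  m <- matrix(c(50, 100, 150, 100, 200, 300), 3,
              dimnames = list(NULL, c("a", "b")))
  cen <- median_center(make_qm(m))
  # column medians {100, 200} -> geometric target 141.42, factors x1.414/x0.707
  expect_equal(apply(cen$values, 2, median), c(a = 141.4214, b = 141.4214),
               tolerance = 1e-6)
  expect_equal(cen$values[, "a"] / m[, 1], rep(sqrt(2), 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  same <- make_qm(matrix(rep(c(10, 20, 30), 2), 3))
  expect_equal(median_center(same)$values, same$values)
  allna <- make_qm(matrix(c(1, 2, NA, NA), 2))
  expect_error(median_center(allna), "no observed")
})

test_that("left-censored imputation substitutes the LOQ and only the LOQ", {
  m <- matrix(c(100, NA, 80, 120, NA, 90), 3,
              dimnames = list(NULL, c("a", "b")))
  qm <- make_qm(m, loq = 50)
  imp <- impute_left_censored(qm)
  expect_equal(sum(is.na(imp$values)), 0)
  expect_equal(imp$values[is.na(m)], c(50, 50))
  expect_equal(imp$values[!is.na(m)], m[!is.na(m)])
  expect_equal(which(imp$imputed), which(is.na(m)))
  # identity when complete; post-imputation min = min(observed min, loq)
  full <- make_qm(matrix(c(60, 70, 80, 90), 2), loq = 50)
  expect_equal(impute_left_censored(full)$values, full$values)
  set.seed(5)
  for (i in 1:10) {
    mm <- matrix(exp(rnorm(40, 5)), 8)
    mm[sample(40, 10)] <- NA
    loq <- runif(1, 1, 200)
    out <- impute_left_censored(make_qm(mm, loq = loq))
    expect_equal(min(out$values), min(min(mm, na.rm = TRUE), loq))
  }
})

test_that("log2 standardization zeroes the Low-group mean and flags the scale", {
  m <- matrix(2^10, 2, 4, dimnames = list(c("p1", "p2"), c("H1", "H2", "L1", "L2")))
  m[1, c("H1", "H2")] <- 2^20     # High = 2^10 x Low
  groups <- c(H1 = "High", H2 = "High", L1 = "Low", L2 = "Low")
  std <- log2_and_standardize(make_qm(m), groups)
  expect_equal(std$scale, "log2_fold_from_low")
  expect_equal(unname(std$values[1, ]), c(10, 10, 0, 0))
  expect_equal(unname(std$values[2, ]), rep(0, 4))   # constant peptide
  expect_equal(unname(rowMeans(std$values[, c("L1", "L2")])), c(0, 0))
  expect_error(log2_and_standardize(std, groups), "already")
})

test_that("standardization is idempotent and imputation leaves observed statistics alone", {
  s <- small_synth(seed = 13, n_features = 400, n_responsive = 50,
                   n_top = 10, n_nuisance = 0)
  qm <- filter_by_detection(s$pep$matrix, s$groups, 0.75)
  proc <- log2_and_standardize(impute_left_censored(median_center(qm)),
                               s$groups)
  # second Low-mean subtraction is a no-op
  lv <- proc$values
  low_cols <- names(s$groups)[s$groups == "Low"]
  expect_equal(lv - rowMeans(lv[, low_cols]), lv, tolerance = 1e-12)
  # a t-statistic computed only on observed cells ignores imputation
  cen <- median_center(qm)
  imp <- impute_left_censored(cen)
  i <- which(rowSums(is.na(cen$values)) > 0)[1]
  obs <- !is.na(cen$values[i, ])
  g <- s$groups[workers(cen)][obs]
  v_before <- cen$values[i, obs]
  v_after <- imp$values[i, obs]
  expect_identical(v_before, v_after)
})

test_that("quant matrix TSV round trip preserves values, mask, LOQ and scale", {
  s <- small_synth(seed = 14, n_features = 50, n_responsive = 10,
                   n_top = 5, n_nuisance = 0)
  qm <- s$pep$matrix
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_matrix(qm, path)
  back <- read_quant_matrix(path)
  expect_equal(back$values, qm$values, tolerance = 1e-12)
  expect_equal(back$intensity_loq, qm$intensity_loq)
  expect_equal(back$scale, "raw")
})
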