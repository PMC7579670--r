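# Confusion matrices and the five evaluation metrics.

test_that("confusion_matrix counts label pairs correctly", {
  cm <- confusion_matrix(c(0, 1, 2, 2), c(0, 1, 2, 3))
  expect_identical(sum(unclass(cm)), 4L)
  expect_identical(cm[3, 3], 1L)
  expect_identical(cm[3, 4], 1L)
  perfect <- confusion_matrix(0:4, 0:4)
  expect_identical(unname(diag(unclass(perfect))), rep(1L, 5))
  expect_identical(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0L)
  empty <- confusion_matrix(integer(0), integer(0))
  expect_true(all(unclass(empty) == 0L))
  expect_error(confusion_matrix(0:2, 0:1), "length")
  expect_error(confusion_matrix(c(0, 5), c(0, 0)), class = "drh_label_error")
})

test_that("the reference confusion matrix fixture has the published margins", {
  cm <- reference_confusion_matrix()
  expect_identical(unname(rowSums(unclass(cm))),
                   c(3673, 346, 752, 123, 106))
  expect_identical(sum(unclass(cm)), 5000L)
  expect_identical(unclass(cm)[1, 1], 3565L)
  expect_equal(unclass(cm), unclass(table4_counts),
               ignore_attr = TRUE)
})

test_that("multiclass accuracy is trace over total", {
  expect_equal(multiclass_accuracy(reference_confusion_matrix()),
               4317 / 5000)
  diag5 <- confusion_matrix(rep(0:4, 2), rep(0:4, 2))
  expect_equal(multiclass_accuracy(diag5), 1)
  off <- confusion_matrix(rep(0, 3), rep(1, 3))
  expect_equal(multiclass_accuracy(off), 0)
  expect_error(multiclass_accuracy(confusion_matrix(integer(0), integer(0))),
               "empty")
})

test_that("binary metrics agree with a pair-counting oracle on random data", {
  set.seed(701)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    truth <- sample(0:4, n, replace = TRUE)
    pred <- sample(0:4, n, replace = TRUE)
    pg <- sample(0:4, 1)
    bm <- binary_metrics(confusion_matrix(truth, pred), pg)
    # oracle: loop over raw label pairs, no matrix involved
    TP <- 0L; TN <- 0L; FP <- 0L; FN <- 0L
    for (k in seq_len(n)) {
      if (truth[k] == pg && pred[k] == pg) TP <- TP + 1L
      else if (truth[k] == pg) FN <- FN + 1L
      else if (pred[k] == pg) FP <- FP + 1L
      else TN <- TN + 1L
    }
    expect_identical(unlist(bm$counts[c("TP", "TN", "FP", "FN")]),
                     c(TP = TP, TN = TN, FP = FP, FN = FN))
    if (TP + FN > 0) expect_equal(bm$sensitivity, TP / (TP + FN))
    if (TP + FP > 0) expect_equal(bm$precision, TP / (TP + FP))
    if (!is.na(bm$f1)) {
      expect_equal(bm$f1,
                   2 * bm$precision * bm$sensitivity /
                     (bm$precision + bm$sensitivity),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate collapses are flagged, never silently zero", {
  cm <- confusion_matrix(c(1, 2, 3), c(1, 2, 3))  # grade 0 never predicted
  bm <- binary_metrics(cm, 0)
  expect_true(is.na(bm$precision))
  expect_true(is.na(bm$sensitivity))             # no actual positives either
  expect_true("precision" %in% bm$undefined)
  d <- binary_metrics(confusion_matrix(0:4, 0:4), 2)
  expect_equal(c(d$sensitivity, d$specificity, d$precision), c(1, 1, 1))
})

test_that("row percentages are row-normalised, rounded, and sum to ~100", {
  pct <- confusion_percentages(reference_confusion_matrix())
  expect_equal(unname(pct[1, ]), c(97.06, 0.98, 1.85, 0.03, 0.08))
  expect_equal(pct[3, 3], 71.81)
  expect_equal(pct[2, 1], 58.96)
  for (i in 1:5) expect_equal(sum(pct[i, ]), 100, tolerance = 0.05)
  diagpct <- confusion_percentages(confusion_matrix(0:4, 0:4))
  expect_equal(unname(diag(diagpct)), rep(100, 5))
  withzero <- unclass(reference_confusion_matrix())
  withzero[2, ] <- 0L
  p2 <- confusion_percentages(structure(withzero, class = "confusion_matrix"))
  expect_true(all(is.na(p2[2, ])))
  expect_identical(attr(p2, "flagged_rows"), 1L)
})

test_that("multiclass accuracy equals frequency-weighted per-row recall", {
  set.seed(702)
  truth <- sample(0:4, 300, replace = TRUE)
  pred <- sample(0:4, 300, replace = TRUE)
  cm <- unclass(confusion_matrix(truth, pred))
  rs <- rowSums(cm)
  recall <- ifelse(rs > 0, diag(cm) / rs, 0)
  expect_equal(multiclass_accuracy(confusion_matrix(truth, pred)),
               sum(recall * rs / sum(rs)), tolerance = 1e-12)
})

test_that("evaluate_model bundles the full report", {
  lbl <- labels_from_counts(table4_counts)
  rep <- evaluate_model(lbl$truth, lbl$pred, positive_grade = 0)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$accuracy, 0.8634, tolerance = 5e-5)
  perfect <- evaluate_model(0:4, 0:4, 0)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity,
                 perfect$precision, perfect$f1), rep(1, 5))
  # grade-4 collapse of the published counts
  bm4 <- binary_metrics(reference_confusion_matrix(), 4)
  expect_equal(bm4$sensitivity, 71 / 106, tolerance = 1e-12)
  out <- withr::local_tempfile(fileext = ".csv")
  write_metrics_report(rep, out)
  expect_equal(read.csv(out)$value[1], rep$accuracy, tolerance = 1e-6)
})
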