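test_that("confusion counts partition the sample", {
  cm <- confusion(c("malignant", "malignant", "benign", "benign"),
                  c("malignant", "benign", "benign", "malignant"))
  expect_equal(cm$TP, 1); expect_equal(cm$FN, 1)
  expect_equal(cm$TN, 1); expect_equal(cm$FP, 1)

  all_right <- confusion(rep(c("benign", "malignant"), 5),
                         rep(c("benign", "malignant"), 5))
  expect_equal(all_right$FP + all_right$FN, 0)

  flipped <- confusion(rep(c("benign", "malignant"), 5),
                       rep(c("malignant", "benign"), 5))
  expect_equal(flipped$TP + flipped$TN, 0)

  expect_error(confusion("benign", c("benign", "benign")), "equal length")
  expect_error(confusion("tumor", "benign"), "labels")
})

test_that("metric formulas and degenerate denominators are exact", {
  m <- metrics(confusion_counts(TP = 50, TN = 40, FP = 5, FN = 5))
  expect_equal(m$accuracy, 0.90)
  expect_equal(round(m$sensitivity, 4), 0.9091)
  expect_equal(round(m$specificity, 4), 0.8889)
  expect_equal(round(m$precision, 4), 0.9091)

  perfect <- metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity",
                                "specificity", "precision")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1, precision = 1))

  deg <- metrics(confusion_counts(TP = 0, TN = 5, FP = 0, FN = 3))
  expect_true(is.na(deg$precision))   # undefined, not zero
  expect_equal(deg$specificity, 1)
  expect_equal(deg$sensitivity, 0)

  td <- tidy(m)
  expect_equal(td$percent[td$metric == "accuracy"], 90)
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  for (s in 1:20) {
    cnt <- withr::with_seed(s, sample(1:40, 4))
    cm <- confusion_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    m <- metrics(cm)
    prev <- (cm$TP + cm$FN) / (cm$TP + cm$TN + cm$FP + cm$FN)
    expect_equal(m$accuracy,
                 prev * m$sensitivity + (1 - prev) * m$specificity)
  }
})

test_that("ROC curves and AUC reproduce worked examples and the rank identity", {
  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1),
                   c("malignant", "malignant", "benign", "benign"))
  expect_equal(sep$auc, 1.0)

  mixed <- roc_curve(c(0.9, 0.8, 0.4, 0.3),
                     c("malignant", "benign", "malignant", "benign"))
  expect_equal(mixed$auc, 0.75)

  ties <- roc_curve(rep(0.5, 6), rep(c("malignant", "benign"), 3))
  expect_equal(ties$auc, 0.5)

  expect_error(roc_curve(c(0.1, 0.2), c("benign", "benign")), "positive")

  # trapezoid AUC == Mann-Whitney AUC on random score sets, including ties
  for (s in 1:200) {
    withr::with_seed(s, {
      n <- sample(4:30, 1)
      truth <- sample(c("benign", "malignant"), n, TRUE)
      if (length(unique(truth)) < 2) truth[1:2] <- c("benign", "malignant")
      scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    })
    expect_equal(roc_curve(scores, truth)$auc, mw_auc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    truth <- sample(c("benign", "malignant"), 60, TRUE)
    truth[1:2] <- c("benign", "malignant")
    scores <- runif(60)
  })
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(truth == "malignant", scores)))
  )
  expect_equal(roc_curve(scores, truth)$auc, ref, tolerance = 1e-12)
})

test_that("error histograms bin signed probability errors per split", {
  # perfect predictions concentrate in the bin containing zero
  eh <- error_histogram(c(1, 1, 0, 0),
                        c("malignant", "malignant", "benign", "benign"),
                        n_bins = 21)
  expect_equal(sum(eh$count), 4)
  expect_equal(eh$count[eh$bin_left <= 0 & eh$bin_right > 0], 4)

  # counts sum to the sample size per split
  withr::with_seed(4, {
    p <- runif(30)
    tr <- sample(c("benign", "malignant"), 30, TRUE)
    sp <- sample(c("train", "val", "test"), 30, TRUE)
  })
  eh2 <- error_histogram(p, tr, sp, n_bins = 10)
  sums <- tapply(eh2$count, eh2$split, sum)
  expect_equal(as.integer(sums[names(table(sp))]), as.integer(table(sp)))

  # constant 0.5 predictions on balanced labels are symmetric around zero
  # odd bin count keeps the binning mirror-symmetric about zero
  eh3 <- error_histogram(rep(0.5, 40), rep(c("benign", "malignant"), 20),
                         n_bins = 21)
  lo <- eh3$count[eh3$bin_mid < -1e-9]
  hi <- rev(eh3$count[eh3$bin_mid > 1e-9])
  expect_equal(lo, hi)
})
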