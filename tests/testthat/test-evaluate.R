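test_that("confusion counts and rates follow the stated definitions", {
  pred <- c("TRUE_IMPACT", "TRUE_IMPACT", "FALSE_EVENT", "FALSE_EVENT",
            "TRUE_IMPACT")
  truth <- c("TRUE_IMPACT", "FALSE_EVENT", "FALSE_EVENT", "TRUE_IMPACT",
             "TRUE_IMPACT")
  cm <- confusion(pred, truth)
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(2, 1, 1, 1))
  expect_equal(cm$sensitivity, 2 / 3)
  expect_equal(cm$specificity, 1 / 2)
  expect_equal(cm$accuracy, 3 / 5)
  expect_equal(cm$precision, 2 / 3)
  expect_equal(cm$npv, 1 / 2)
  expect_equal(cm$n, 5)
})

test_that("perfect predictions score 1.0 on every metric", {
  truth <- rep(c("TRUE_IMPACT", "FALSE_EVENT"), c(7, 9))
  cm <- confusion(truth, truth)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$precision, 1)
  expect_equal(cm$npv, 1)
})

test_that("derived metrics are self-consistent with counts on fuzzed tables", {
  set.seed(101)
  for (i in 1:50) {
    k <- as.list(stats::setNames(sample(0:80, 4, replace = TRUE),
                                 c("tp", "fp", "tn", "fn")))
    if (sum(unlist(k)) == 0) next
    cm <- confusion(counts = k)
    td <- tidy(cm)
    expect_equal(td$n, k$tp + k$fp + k$tn + k$fn)
    if (k$tp + k$fn > 0) expect_equal(td$sensitivity, k$tp / (k$tp + k$fn))
    if (k$tn + k$fp > 0) expect_equal(td$specificity, k$tn / (k$tn + k$fp))
    expect_equal(td$accuracy, (k$tp + k$tn) / td$n)
    # accuracy is a prevalence-weighted mean of sensitivity and specificity
    if (k$tp + k$fn > 0 && k$tn + k$fp > 0) {
      expect_gte(td$accuracy, min(td$sensitivity, td$specificity) - 1e-12)
      expect_lte(td$accuracy, max(td$sensitivity, td$specificity) + 1e-12)
    }
  }
})

test_that("rates are invariant under test-set duplication; accuracy under permutation", {
  set.seed(102)
  pred <- sample(c("TRUE_IMPACT", "FALSE_EVENT"), 40, replace = TRUE)
  truth <- sample(c("TRUE_IMPACT", "FALSE_EVENT"), 40, replace = TRUE)
  cm1 <- confusion(pred, truth)
  cm2 <- confusion(rep(pred, 2), rep(truth, 2))
  expect_equal(cm2$sensitivity, cm1$sensitivity)
  expect_equal(cm2$specificity, cm1$specificity)
  perm <- sample(40)
  cm3 <- confusion(pred[perm], truth[perm])
  expect_equal(cm3$accuracy, cm1$accuracy)
})

test_that("zero-denominator metrics are flagged NA, never silently zero", {
  cm <- confusion(counts = c(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(cm$sensitivity))
  expect_true(is.na(cm$precision))
  expect_setequal(cm$undefined, c("sensitivity", "precision"))
  expect_equal(format_confusion(cm)$Sensitivity, "NA")
  expect_equal(format_confusion(cm)$Specificity, "100%")
})

test_that("invalid evaluation inputs raise errors", {
  expect_error(confusion(c("TRUE_IMPACT"), c("TRUE_IMPACT", "FALSE_EVENT")),
               "different lengths")
  expect_error(confusion(c("TRUE_IMPACT"), c("UNVERIFIED")), "UNVERIFIED")
  expect_error(confusion(c("YES"), c("TRUE_IMPACT")), "unknown label")
})

test_that("rendering follows the printed-table conventions", {
  cm <- confusion(counts = c(tp = 35, fp = 5, tn = 410, fn = 15))
  fc <- format_confusion(cm)
  expect_equal(fc$Sensitivity, "70%")
  expect_equal(fc$Specificity, "99%")   # 98.8 rounds to 99
  expect_equal(fc$Accuracy, "96%")      # 95.7 rounds to 96
  expect_equal(fc$PPV, "0.88")          # 0.875 rounds half up
  expect_equal(fc$NPV, "0.96")
})

test_that("compare_models renders one row per report in documented column order", {
  reports <- list(
    m4 = confusion(counts = c(tp = 38, fp = 6, tn = 409, fn = 12)),
    svm = confusion(counts = c(tp = 30, fp = 10, tn = 405, fn = 20)))
  tab <- compare_models(reports)
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab),
               c("model", "TP", "FP", "TN", "FN", "Sensitivity",
                 "Specificity", "Accuracy", "PPV", "NPV"))
  expect_equal(tab$model, c("m4", "svm"))
  unnamed <- compare_models(unname(reports))
  expect_equal(unnamed$model, c("model_1", "model_2"))
})
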