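test_that("confusion counts match hand enumeration", {
  y <- c(1, 1, 1, 0, 0, 0, 1, 0)
  p <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2, 0.4, 0.6)
  cc <- confusion_at_threshold(y, p, 0.5)
  expect_equal(cc, list(TP = 3L, TN = 3L, FP = 1L, FN = 1L))
  # threshold 0: everything predicted positive
  cc0 <- confusion_at_threshold(y, p, 0)
  expect_equal(cc0$TN + cc0$FN, 0L)
  expect_error(confusion_at_threshold(y, p[-1]), "lengths differ")
})

test_that("AUROC equals pairwise concordance enumeration", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.3)), 0.5)
  brute <- function(y, p) {
    pos <- p[y == 1]; neg <- p[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(10)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(auroc(y, p), brute(y, p))
  }
  expect_error(auroc(rep(1, 5), runif(5)), "one class")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(11)
  y <- rbinom(50, 1, 0.4); p <- runif(50)
  expect_equal(auroc(y, qlogis(p * 0.98 + 0.01)), auroc(y, p))
  expect_equal(auroc(y, p^3), auroc(y, p))
})

test_that("ROC curve is anchored, monotone, and integrates to the AUROC", {
  set.seed(12)
  y <- rbinom(40, 1, 0.5); p <- runif(40)
  roc <- roc_curve(y, p)
  expect_equal(unlist(roc[1, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(roc[nrow(roc), c("fpr", "tpr")], use.names = FALSE),
               c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(attr(roc, "area"), auroc(y, p))
})

test_that("agreement with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  y <- rbinom(60, 1, 0.5); p <- runif(60)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, direction = "<",
                                        levels = c(0, 1), quiet = TRUE)))
  expect_equal(auroc(y, p), ref, tolerance = 1e-12)
})

test_that("precision/recall/F1/MCC/Brier match their hand-computed values", {
  cc <- list(TP = 3L, TN = 3L, FP = 1L, FN = 1L)
  prf <- precision_recall_f1(cc)
  expect_equal(prf, list(precision = 0.75, recall = 0.75, f1 = 0.75))
  expect_equal(mcc(cc), 0.5)
  expect_equal(brier(c(1, 0), c(0.9, 0.1)), 0.01)
  expect_equal(brier(c(1, 0), c(1, 0)), 0)
  expect_equal(brier(c(1, 0, 1), rep(0.5, 3)), 0.25)
  # boundary conventions
  expect_equal(mcc(list(TP = 0L, TN = 5L, FP = 0L, FN = 5L)), 0)
  expect_equal(mcc(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L)), 1)
  expect_equal(mcc(list(TP = 0L, TN = 0L, FP = 5L, FN = 5L)), -1)
  expect_warning(prf0 <- precision_recall_f1(list(TP = 0L, TN = 4L, FP = 0L,
                                                  FN = 2L)), "precision")
  expect_equal(prf0$precision, 0)
  expect_equal(prf0$f1, 0)
})

test_that("metrics from counts agree with brute-force recomputation", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- runif(n)
    cc <- confusion_at_threshold(y, p, 0.5)
    pred <- as.integer(p >= 0.5)
    expect_equal(cc$TP, sum(pred & y))
    expect_equal(cc$TN, sum(!pred & !y))
    rep_all <- suppressWarnings(evaluate_all(y, p, 0.5))
    expect_equal(rep_all$accuracy, mean(pred == y))
    expect_gte(rep_all$mcc, -1); expect_lte(rep_all$mcc, 1)
  }
})

test_that("a perfect classifier maxes every metric", {
  y <- c(1, 1, 0, 0)
  p <- c(0.99, 0.98, 0.01, 0.02)
  rep_all <- evaluate_all(y, p)
  expect_equal(rep_all$auroc, 1)
  expect_equal(rep_all$accuracy, 1)
  expect_equal(rep_all$f1, 1)
  expect_equal(rep_all$mcc, 1)
  expect_lt(rep_all$brier, 1e-3)
})

test_that("metric reports survive JSON round trips", {
  rep_all <- evaluate_all(c(1, 0, 1, 0), c(0.8, 0.3, 0.6, 0.4))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rep_all, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path)
  expect_equal(back$auroc, rep_all$auroc, tolerance = 1e-12)
  expect_equal(back$brier, rep_all$brier, tolerance = 1e-12)
  expect_equal(back$mcc, rep_all$mcc, tolerance = 1e-12)
})
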