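test_that("confusion counts cover all outcome patterns and conserve n", {
  expect_identical(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)),
                   c(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  expect_identical(confusion_counts(c(1, 0), c(1, 1)),
                   c(tp = 1L, tn = 0L, fp = 1L, fn = 0L))
  # exhaustive over every truth/prediction pattern of length 4
  grid <- expand.grid(rep(list(0:1), 4))
  for (a in seq_len(nrow(grid))) {
    for (b in seq_len(nrow(grid))) {
      truth <- as.integer(grid[a, ]); pred <- as.integer(grid[b, ])
      cm <- confusion_counts(truth, pred)
      expect_identical(sum(cm), 4L)
      expect_identical(cm[["tp"]], sum(truth & pred))
      expect_identical(cm[["tn"]], sum(!truth & !pred))
    }
  }
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
  expect_error(confusion_counts(1, c(1, 0)), "equal length")
})

test_that("metric formulas match independent hand computation", {
  perfect <- compute_metrics(c(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(unname(perfect), rep(1, 6))

  # all-negative predictor on balanced data
  deg <- suppressWarnings(
    compute_metrics(c(tp = 0, tn = 50, fp = 0, fn = 50)))
  expect_equal(deg[["acc"]], 0.5)
  expect_equal(deg[["sn"]], 0)
  expect_equal(deg[["sp"]], 1)
  expect_equal(deg[["mcc"]], 0)

  m <- compute_metrics(c(tp = 40, tn = 30, fp = 20, fn = 10))
  o <- metrics_oracle(40, 30, 20, 10)
  expect_equal(m[["acc"]], o$acc)   # 70/100
  expect_equal(m[["sn"]], o$sn)     # 40/50
  expect_equal(m[["sp"]], o$sp)     # 30/50
  expect_equal(m[["pre"]], o$pre)   # 40/60
  expect_equal(m[["f"]], 80 / 110)
  expect_equal(m[["mcc"]], o$mcc)
})

test_that("every zero/nonzero boundary pattern yields defined, in-range metrics", {
  cells <- expand.grid(tp = c(0, 3), tn = c(0, 5), fp = c(0, 2), fn = c(0, 4))
  for (i in seq_len(nrow(cells))) {
    cm <- unlist(cells[i, ])
    if (sum(cm) == 0) {
      expect_error(compute_metrics(cm), "empty")
      next
    }
    m <- suppressWarnings(compute_metrics(cm))
    o <- metrics_oracle(cm[["tp"]], cm[["tn"]], cm[["fp"]], cm[["fn"]])
    expect_equal(unname(m), unname(unlist(o)))
    expect_true(all(m[c("acc", "sn", "sp", "pre", "f")] >= 0 &
                    m[c("acc", "sn", "sp", "pre", "f")] <= 1))
    expect_gte(m[["mcc"]], -1); expect_lte(m[["mcc"]], 1)
    # accuracy conservation: ACC * total = TP + TN exactly
    expect_equal(m[["acc"]] * sum(cm), cm[["tp"]] + cm[["tn"]])
  }
})

test_that("F equals the harmonic mean of precision and sensitivity; MCC is class-swap symmetric", {
  set.seed(61)
  for (i in 1:25) {
    cm <- c(tp = sample(0:20, 1), tn = sample(0:20, 1),
            fp = sample(0:20, 1), fn = sample(0:20, 1))
    if (sum(cm) == 0) next
    m <- suppressWarnings(compute_metrics(cm))
    if (m[["pre"]] > 0 && m[["sn"]] > 0) {
      expect_equal(m[["f"]],
                   2 * m[["pre"]] * m[["sn"]] / (m[["pre"]] + m[["sn"]]))
    }
    swapped <- suppressWarnings(
      compute_metrics(c(tp = cm[["tn"]], tn = cm[["tp"]],
                        fp = cm[["fn"]], fn = cm[["fp"]])))
    expect_equal(m[["mcc"]], swapped[["mcc"]])
  }
})

test_that("ROC curve endpoints, tie grouping and rank invariance", {
  truth <- c(1, 1, 0, 0)
  sep <- c(0.9, 0.8, 0.2, 0.1)
  curve <- roc_curve(truth, sep)
  expect_identical(curve$fpr[1], 0); expect_identical(curve$tpr[1], 0)
  expect_identical(curve$fpr[nrow(curve)], 1)
  expect_identical(curve$tpr[nrow(curve)], 1)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))  # passes through (0,1)
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
  expect_equal(roc_auc(truth, sep), 1)

  # all-tied scores: the diagonal
  flat <- roc_curve(truth, rep(0.5, 4))
  expect_identical(nrow(flat), 2L)
  expect_equal(roc_auc(truth, rep(0.5, 4)), 0.5)

  # monotone transform leaves the curve unchanged
  set.seed(71)
  sc <- runif(30)
  tr <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(roc_curve(tr, sc)[c("fpr", "tpr")],
               roc_curve(tr, sc^3 + 2)[c("fpr", "tpr")])
  expect_error(roc_curve(rep(1, 4), runif(4)), "each class")
})

test_that("trapezoidal AUC equals the all-pairs rank statistic", {
  set.seed(81)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(round(runif(n), 2))  # rounding forces ties
    expect_equal(roc_auc(truth, scores), auc_pairs_oracle(truth, scores))
    # complement symmetry for tie-free scores
    tf <- seq_len(n) / n
    tf <- sample(tf)
    expect_equal(roc_auc(truth, tf) + roc_auc(truth, -tf), 1)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  truth <- sample(0:1, 80, replace = TRUE)
  truth[1:2] <- c(0, 1)
  scores <- round(runif(80), 2)
  expect_equal(roc_auc(truth, scores),
               as.numeric(pROC::auc(pROC::roc(
                 truth, scores, quiet = TRUE,
                 levels = c(0, 1), direction = "<"))))
})

test_that("evaluation report applies the strict decision threshold", {
  truth <- c(1, 0, 1, 0)
  scores <- c(0.9, 0.5, 0.5, 0.1)
  rep <- evaluate_predictions(truth, scores)
  # scores exactly at 0.5 are called negative
  expect_identical(rep$counts,
                   c(tp = 1L, tn = 2L, fp = 0L, fn = 1L))
  expect_identical(rep$n, 4L)
  expect_s3_class(rep, "phos_metrics")
  expect_output(print(rep), "ACC")
})
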