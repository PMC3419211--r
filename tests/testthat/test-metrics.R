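test_that("Recall depends only on TP/FN and validates its domain", {
  expect_equal(recall_pct(confusion_counts(tp = 9, fp = 0, tn = 0, fn = 1)), 90)
  expect_equal(recall_pct(confusion_counts(tp = 0, fp = 3, tn = 2, fn = 5)), 0)
  expect_equal(recall_pct(confusion_counts(tp = 7, fp = 11, tn = 23, fn = 3)),
               recall_pct(confusion_counts(tp = 7, fp = 0, tn = 999, fn = 3)))
  expect_error(recall_pct(confusion_counts(tp = 0, fp = 1, tn = 1, fn = 0)),
               "undefined")
})

test_that("Mean error is the balanced error rate", {
  expect_equal(mean_error_pct(confusion_counts(tp = 5, fp = 0, tn = 5, fn = 0)), 0)
  expect_equal(mean_error_pct(confusion_counts(tp = 0, fp = 10, tn = 0, fn = 10)), 100)
  expect_equal(mean_error_pct(confusion_counts(tp = 8, fp = 10, tn = 90, fn = 2)), 15)
  expect_error(mean_error_pct(confusion_counts(tp = 3, fp = 0, tn = 0, fn = 1)))
  # complement of balanced accuracy, and scale invariance, over random counts
  withr::with_seed(1, for (i in 1:20) {
    c0 <- confusion_counts(tp = sample(1:50, 1), fp = sample(0:50, 1),
                           tn = sample(1:50, 1), fn = sample(0:50, 1))
    bal_acc <- 0.5 * (c0$tp / (c0$tp + c0$fn) + c0$tn / (c0$tn + c0$fp))
    expect_equal(mean_error_pct(c0), 100 - 100 * bal_acc)
    c3 <- confusion_counts(tp = 3 * c0$tp, fp = 3 * c0$fp,
                           tn = 3 * c0$tn, fn = 3 * c0$fn)
    expect_equal(recall_pct(c3), recall_pct(c0))
    expect_equal(mean_error_pct(c3), mean_error_pct(c0))
  })
})

test_that("fold aggregation macro-averages per-fold metrics", {
  f <- confusion_counts(tp = 8, fp = 2, tn = 18, fn = 2)
  agg <- aggregate_folds(list(f, f, f))
  expect_equal(agg$recall_pct, recall_pct(f))
  expect_equal(agg$mean_error_pct, mean_error_pct(f))

  two <- aggregate_folds(list(confusion_counts(tp = 4, fp = 0, tn = 10, fn = 1),
                              confusion_counts(tp = 5, fp = 0, tn = 10, fn = 0)))
  expect_equal(two$recall_pct, 90)
  expect_error(aggregate_folds(list()))

  # pooled (micro) counts are exposed alongside, not instead
  pooled <- aggregate_folds(list(confusion_counts(tp = 1, fp = 0, tn = 5, fn = 1),
                                 confusion_counts(tp = 6, fp = 0, tn = 5, fn = 0)),
                            pooled = TRUE)
  expect_equal(pooled$recall_pct, mean(c(50, 100)))
  expect_equal(pooled$pooled_recall_pct, 100 * 7 / 8)
})

test_that("table deltas compute paired means with half-up rounding", {
  same <- data.frame(recall = c(80, 90), mean_error = c(10, 20))
  expect_equal(unname(table_deltas(same, same)), c(0, 0))
  after <- data.frame(recall = c(85, 96), mean_error = c(7, 14))
  expect_equal(unname(table_deltas(same, after)), c(5.5, 4.5))
  expect_error(table_deltas(same, after[1, ]))
  # half-up at the second decimal
  expect_equal(unname(table_deltas(data.frame(recall = 0, mean_error = 0),
                                   data.frame(recall = 0.125, mean_error = 0))[1]),
               0.13)
})
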