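test_that("confusion counts match hand tallies and conserve pixels", {
  truth <- matrix(c(0L, 1L, 2L, 2L), 2, 2)
  pred <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  cm <- confusion_counts(pred, truth, 3)
  expect_equal(unname(diag(unclass(cm))), c(1, 1, 1))
  expect_equal(unclass(cm)[3, 2], 1)
  expect_equal(sum(cm), 4)
  expect_equal(sum(unclass(cm)[3, ]), 2)
  # identical masks give a diagonal matrix
  cm2 <- confusion_counts(truth, truth, 3)
  expect_equal(sum(unclass(cm2)) - sum(diag(unclass(cm2))), 0)
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 2), 3),
               "shape")
  expect_error(confusion_counts(matrix(5L, 2, 2), matrix(0L, 2, 2), 3),
               "range")
})

test_that("per-class metrics follow the TP/FP/FN definitions", {
  # TP = 3, FP = 1, FN = 0 for class 0
  cm <- matrix(c(3, 0, 1, 2), 2, 2, byrow = TRUE)
  rep <- class_metrics(cm)
  expect_equal(rep$per_class$iou[1], 0.75)
  expect_equal(rep$per_class$precision[1], 0.75)
  expect_equal(rep$per_class$recall[1], 1.0)
  expect_equal(rep$per_class$f1[1], 6 / 7)
  # perfect prediction
  perfect <- class_metrics(diag(c(5, 3, 2)))
  expect_equal(perfect$miou, 1)
  expect_true(all(unlist(perfect$per_class[, -1]) == 1))
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(1)
  for (i in 1:100) {
    cm <- matrix(rpois(9, 20), 3, 3)
    if (sum(cm) == 0) next
    rep <- suppressWarnings(class_metrics(cm))
    pc <- rep$per_class
    ok <- !is.na(pc$iou)
    expect_true(all(abs(pc$f1[ok] - 2 * pc$iou[ok] / (1 + pc$iou[ok]))
                    < 1e-12))
    expect_true(all(pc$iou[ok] <= pc$precision[ok] + 1e-15))
    expect_true(all(pc$iou[ok] <= pc$recall[ok] + 1e-15))
    expect_true(all(unlist(pc[ok, -1]) >= 0 & unlist(pc[ok, -1]) <= 1))
    rs <- rowSums(rep$confusion_norm)
    nonempty <- rowSums(cm) > 0
    expect_true(all(abs(rs[nonempty] - 1) < 1e-12))
  }
})

test_that("classes absent from prediction and truth are excluded from mIoU", {
  cm <- matrix(0, 3, 3)
  cm[1, 1] <- 10; cm[2, 2] <- 5; cm[2, 1] <- 1
  expect_warning(rep <- class_metrics(cm), "absent")
  expect_true(is.na(rep$per_class$iou[3]))
  expect_equal(rep$miou, mean(rep$per_class$iou[1:2]))
})

test_that("tidy and glance return the expected tabular summaries", {
  rep <- class_metrics(diag(c(4, 4, 4)))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(rep)
  expect_equal(gl$miou, 1)
  expect_equal(gl$n_pixels, 12)
})
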