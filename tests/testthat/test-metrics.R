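test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion_matrix(c("Normal", "AF", "AF"), c("Normal", "AF", "AF"))
  expect_equal(sum(diag(cm)), 3L)
  expect_equal(sum(cm), 3L)
  cm2 <- confusion_matrix("AF", "Bradycardia")
  expect_equal(cm2["AF", "Bradycardia"], 1L)
  expect_equal(sum(cm2), 1L)
  expect_error(confusion_matrix(c("AF", "Normal"), "AF"), "equal length")
})

test_that("per-class metrics follow the precision/recall/F1 definitions", {
  cm <- diag(c(5L, 3L, 2L, 1L))
  dimnames(cm) <- list(true = rhythm_classes(), pred = rhythm_classes())
  pm <- per_class_metrics(cm)
  expect_true(all(pm$per_class$precision == 1))
  expect_true(all(pm$per_class$recall == 1))
  expect_true(all(pm$per_class$f1 == 1))
  expect_equal(pm$accuracy, 1)
  # zero-denominator convention: an unpredicted class scores 0
  cm0 <- matrix(0L, 4, 4,
                dimnames = list(true = rhythm_classes(),
                                pred = rhythm_classes()))
  cm0[1, 1] <- 10L; cm0[2, 1] <- 5L
  pm0 <- per_class_metrics(cm0)
  expect_equal(pm0$per_class$f1[2], 0)
  # weighted identity: accuracy = sum_j recall_j * rowsum_j / n
  cmw <- worked_confusion()
  pmw <- per_class_metrics(cmw)
  expect_equal(pmw$accuracy,
               sum(pmw$per_class$recall * rowSums(cmw)) / sum(cmw))
})

test_that("segmentation metrics honour overlap definitions and conventions", {
  a <- c(rep(1, 50), rep(0, 50))
  expect_equal(seg_metrics(a, a)$dice, 1)
  expect_equal(seg_metrics(a, a)$iou, 1)
  b <- c(rep(0, 50), rep(1, 50))
  expect_equal(seg_metrics(a, b)$dice, 0)
  expect_equal(seg_metrics(a, b)$iou, 0)
  # ones on [0,100) vs [50,150): dice 0.5, iou 1/3
  t1 <- c(rep(1, 100), rep(0, 186))
  p1 <- c(rep(0, 50), rep(1, 100), rep(0, 136))
  sm <- seg_metrics(p1, t1)
  expect_equal(sm$dice, 0.5)
  expect_equal(sm$iou, 1 / 3)
  # both-empty convention
  z <- rep(0, 286)
  expect_equal(seg_metrics(z, z)$dice, 1)
  expect_equal(seg_metrics(z, z)$iou, 1)
  expect_error(seg_metrics(c(0, 2), c(0, 1)), "binary")
})

test_that("improvement arithmetic matches its definitions", {
  expect_equal(relative_improvement(1.2, 1.0), 20)
  expect_equal(relative_improvement(5, 5), 0)
  expect_equal(absolute_improvement(0.95, 0.90), 5, tolerance = 1e-9)
  expect_error(relative_improvement(1, 0), "undefined")
})

test_that("patient-level splits are exact, disjoint and reproducible", {
  ids <- sprintf("P%02d", 1:35)
  sp <- patient_level_split(ids, seed = 3)
  expect_length(sp$train, 22L)
  expect_length(sp$val, 8L)
  expect_length(sp$test, 5L)
  expect_length(intersect(sp$train, c(sp$val, sp$test)), 0L)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(patient_level_split(ids, seed = 3), sp)
  expect_error(patient_level_split(ids, fractions = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("stratified splits place every large stratum in every fold", {
  ids <- sprintf("P%02d", 1:24)
  strata <- stats::setNames(rep(c("Normal", "AF", "Bradycardia"), each = 8),
                            ids)
  sp <- patient_level_split(ids, seed = 5, strata = strata)
  for (cl in c("Normal", "AF", "Bradycardia")) {
    for (fold in sp) expect_true(any(strata[fold] == cl))
  }
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
})

test_that("segments inherit their patient's fold", {
  segs <- test_prep()$segments
  ids <- unique(vapply(segs, `[[`, "", "patient_id"))
  sp <- patient_level_split(ids, seed = 2)
  folds <- split_segments(segs, sp)
  for (f in names(folds)) {
    pid <- unique(vapply(folds[[f]], `[[`, "", "patient_id"))
    expect_true(all(pid %in% sp[[f]]))
  }
  expect_equal(sum(lengths(folds)), length(segs))
})
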