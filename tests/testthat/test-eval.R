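test_that("segment prediction applies argmax, fake-exclusion and tie rules", {
  probs <- rbind(c(0.7, 0.2, 0.1),
                 c(0.2, 0.3, 0.5),    # fake argmax -> higher real class
                 c(0.25, 0.25, 0.5),  # real-class tie -> class 0
                 c(0.1, 0.6, 0.3))
  expect_identical(predict_from_probs(probs), c(0L, 1L, 0L, 1L))
  # 2-column (CNN) probabilities: plain argmax
  expect_identical(predict_from_probs(rbind(c(0.6, 0.4), c(0.3, 0.7))),
                   c(0L, 1L))
})

test_that("untrained classifiers warn when asked to predict", {
  clf <- build_classifier(2, 640, rng_seed = 1)
  expect_warning(predict_segments(clf, matrix(0, 1, 640)), "not been trained")
})

test_that("confusion counts treat tendency (label 1) as positive", {
  truth <- rep(c(1, 0), c(60, 140))
  perfect <- confusion(truth, truth)
  expect_identical(unlist(perfect[c("TP", "TN", "FP", "FN")]),
                   c(TP = 60L, TN = 140L, FP = 0L, FN = 0L))
  all0 <- confusion(rep(0, 200), truth)
  expect_identical(unlist(all0[c("TP", "TN", "FP", "FN")]),
                   c(TP = 0L, TN = 140L, FP = 0L, FN = 60L))
  expect_error(confusion(c(0, 1), c(0, 1, 1)))
  expect_error(confusion(c(0, 2), c(0, 1)), "0/1")
})

test_that("rates reproduce the reference six-task cells exactly", {
  counts <- reference_task_counts()
  expect_equal(percent(vapply(counts, accuracy, 0)),
               c(A = 92.0, B = 96.0, C = 93.5, D = 92.5, E = 93.5, F = 99.0))
  expect_equal(percent(vapply(counts, specificity, 0)),
               c(A = 92.1, B = 97.1, C = 95.7, D = 92.1, E = 94.3, F = 99.3))
  expect_equal(percent(vapply(counts, sensitivity, 0)),
               c(A = 91.7, B = 93.3, C = 88.3, D = 93.3, E = 91.7, F = 98.3))
  # row A spelled out
  a <- counts$A
  expect_equal(accuracy(a), 184 / 200)
  expect_equal(specificity(a), 129 / 140)
  expect_equal(sensitivity(a), 55 / 60)
})

test_that("zero denominators give NA with a warning", {
  empty <- confusion_counts(0, 0, 0, 0)
  expect_warning(expect_true(is.na(accuracy(empty))), "undefined")
  expect_warning(expect_true(is.na(specificity(empty))), "undefined")
  no_pos <- confusion_counts(0, 5, 2, 0)
  expect_warning(expect_true(is.na(sensitivity(no_pos))), "undefined")
})

test_that("macro aggregation reproduces the reference averages", {
  rep6 <- aggregate_tasks(reference_task_counts())
  expect_equal(percent(rep6$average$accuracy), 94.4)
  expect_equal(percent(rep6$average$specificity), 95.1)
  # the macro mean of the per-task sensitivities rounds to 92.8
  expect_equal(percent(rep6$average$sensitivity), 92.8)
  expect_equal(rep6$average$FP, 41 / 6)
  one <- aggregate_tasks(reference_task_counts()["C"])
  expect_equal(one$average$accuracy, one$per_task$accuracy)
  expect_equal(one$average$sensitivity, one$per_task$sensitivity)
})

test_that("rate identities and bounds hold for arbitrary counts", {
  set.seed(14)
  for (i in 1:50) {
    v <- stats::rpois(4, 20) + 1
    cc <- confusion_counts(v[1], v[2], v[3], v[4])
    acc <- accuracy(cc); spc <- specificity(cc); sen <- sensitivity(cc)
    expect_true(all(c(acc, spc, sen) >= 0 & c(acc, spc, sen) <= 1))
    total <- v[1] + v[2] + v[3] + v[4]
    expect_equal(acc,
                 (sen * (cc$TP + cc$FN) + spc * (cc$TN + cc$FP)) / total,
                 tolerance = 1e-12)
  }
})

test_that("percent formatting rounds halves up to one decimal", {
  expect_equal(percent(0.92142857), 92.1)
  expect_equal(percent(0.9215), 92.2)
  expect_equal(percent(0.98333333), 98.3)
  expect_equal(percent(0.944166667), 94.4)
})

test_that("the warning rule fires on the configured fraction of tendency segments", {
  expect_identical(warning_decision(rep(c(1, 0), c(13, 11))), "warn")
  expect_identical(warning_decision(rep(0, 24)), "no_warn")
  expect_identical(warning_decision(rep(c(1, 0), c(1, 23)), 1 / 24), "warn")
  expect_identical(warning_decision(rep(c(1, 0), c(11, 13))), "no_warn")
  expect_error(warning_decision(integer(0)), "no segment")
})
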