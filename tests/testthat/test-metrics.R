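test_that("confusion matrices count exactly", {
  y <- c(1, 2, 3, 2, 1)
  expect_equal(confusion_matrix(y, y, 3), diag(c(2L, 2L, 1L)),
               ignore_attr = TRUE)
  cm <- confusion_matrix(c(2, 2, 3), c(1, 1, 1), 3)
  expect_equal(sum(diag(cm)), 0)
  expect_equal(colSums(cm), c(3L, 0L, 0L), ignore_attr = TRUE)
  expect_error(confusion_matrix(c(1, 4), c(1, 1), 3), "out of range")

  set.seed(14)
  yt <- sample(1:4, 50, TRUE); yp <- sample(1:4, 50, TRUE)
  cm <- confusion_matrix(yt, yp, 4)
  ref <- matrix(0L, 4, 4)
  for (i in 1:50) ref[yt[i], yp[i]] <- ref[yt[i], yp[i]] + 1L
  expect_equal(cm, ref)
  expect_equal(sum(cm), 50)
})

test_that("published 3-class worked-example rows reproduce exactly", {
  pub <- published_best_model_counts("smids")
  comp <- metrics_from_counts(pub$counts$tp, pub$counts$fp, pub$counts$fn)
  expect_equal(round_half_up(comp$precision, 2), pub$counts$precision)
  expect_equal(round_half_up(comp$recall, 2), pub$counts$recall)
  expect_equal(round_half_up(comp$f1, 2), pub$counts$f1)
  expect_equal(round_half_up(mean(comp$f1), 2), 96.17)
  expect_equal(round_half_up(mean(comp$precision), 2), pub$macro_precision)
})

test_that("published 4-class worked-example rows reproduce exactly", {
  pub <- published_best_model_counts("hushem")
  comp <- metrics_from_counts(pub$counts$tp, pub$counts$fp, pub$counts$fn)
  expect_equal(round_half_up(comp$precision, 2), pub$counts$precision)
  expect_equal(round_half_up(comp$recall, 2), pub$counts$recall)
  expect_equal(round_half_up(comp$f1, 2), pub$counts$f1)
  expect_equal(round_half_up(mean(comp$f1), 2), 95.68)
  expect_equal(round_half_up(mean(comp$recall), 2), pub$macro_recall)
  expect_true(verify_published_tables(quiet = TRUE)$all_match)
})

test_that("degenerate counts follow the 0/0 -> 0 convention", {
  # both the precision and the recall ratio degenerate, one warning each
  expect_warning(expect_warning(out <- metrics_from_counts(0, 0, 0), "0/0"))
  expect_equal(out$precision, 0)
  expect_equal(out$f1, 0)
})

test_that("macro metrics are unweighted means of per-class values", {
  set.seed(15)
  cm <- confusion_matrix(sample(1:3, 60, TRUE), sample(1:3, 60, TRUE), 3)
  rep <- suppressWarnings(classwise_metrics(cm))
  expect_equal(rep$macro_f1, mean(rep$per_class$f1), tolerance = 1e-9)
  expect_equal(rep$accuracy, 100 * sum(diag(cm)) / sum(cm))
})

test_that("McNemar's test follows the continuity-corrected formula", {
  y <- rep(1, 20)
  predA <- rep(1, 20)
  predB <- c(rep(2, 10), rep(1, 10))  # b = 10, c = 0
  mc <- mcnemar_test(y, predA, predB)
  expect_equal(mc$statistic, 81 / 10)
  expect_equal(mc$b, 10)

  # b == c: statistic collapses to 1/(2b) and p is large
  y2 <- rep(1, 10)
  pa <- c(rep(2, 3), rep(1, 7))
  pb <- c(rep(1, 3), rep(2, 3), rep(1, 4))  # b = 3, c = 3
  mc2 <- mcnemar_test(y2, pa, pb)
  expect_equal(mc2$statistic, 1 / 6)
  expect_gt(mc2$p_value, 0.5)
  # symmetry in the two classifiers
  sw <- mcnemar_test(y2, pb, pa)
  expect_equal(sw$statistic, mc2$statistic)

  expect_equal(mcnemar_test(y, predA, predA),
               list(statistic = 0, p_value = 1, b = 0, c = 0))

  # cross-check against the standard contingency-table implementation
  tab <- matrix(c(7, 0, 10, 3), 2)  # discordant cells 10 and 0
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(mc$statistic, unname(ref$statistic))
  expect_equal(mc$p_value, unname(ref$p.value))
})

test_that("stratified folds balance classes and are reproducible", {
  y <- rep(1:3, each = 10)
  folds <- stratified_kfold(y, 5, seed = 2)
  expect_length(folds, 5)
  for (f in folds) expect_equal(unname(table(y[f])), rep(2L, 3),
                                ignore_attr = TRUE)
  expect_equal(sort(unlist(folds)), 1:30)
  expect_identical(folds, stratified_kfold(y, 5, seed = 2))
  expect_false(identical(folds, stratified_kfold(y, 5, seed = 3)))
  expect_error(stratified_kfold(c(1, 1, 2), 3, 1), "fewer than")
})

test_that("CV summaries report both interval conventions", {
  # five folds engineered to mean 94.50, sd 1.18
  folds <- c(94.5, 94.5, 94.5, 94.5 - 1.18 * sqrt(2), 94.5 + 1.18 * sqrt(2))
  s <- cv_summary(folds)
  expect_equal(s$mean, 94.5)
  expect_equal(s$sd, 1.18, tolerance = 1e-12)
  expect_equal(round_half_up(s$interval_mean_sd, 2), c(93.32, 95.68))
  # the t-based CI is tighter labeled differently
  expect_true(s$ci95_t[1] > s$interval_mean_sd[1] - 2)

  s2 <- cv_summary(c(90, 100))
  expect_equal(s2$mean, 95)
  expect_equal(s2$sd, sqrt(50), tolerance = 1e-9)
  expect_equal(round_half_up(s2$interval_mean_sd, 2), c(87.93, 102.07))

  s3 <- cv_summary(c(88, 88, 88))
  expect_equal(s3$sd, 0)
  expect_equal(s3$interval_mean_sd, c(88, 88))
  expect_error(cv_summary(95), "at least 2")
})
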