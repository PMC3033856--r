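test_that("scoring agrees with independent arithmetic on random matrices", {
  withr::with_seed(61, {
    for (i in 1:20) {
      cells <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                       c("tp", "fn", "tn", "fp")))
      if (cells$tp + cells$fn == 0 || cells$tn + cells$fp == 0) next
      r <- score_confusion(cells)
      n <- with(cells, tp + fn + tn + fp)
      st <- 100 * cells$tp / (cells$tp + cells$fn)
      sp <- 100 * cells$tn / (cells$tn + cells$fp)
      pa <- (cells$tp + cells$tn) / n
      pe <- ((cells$tp + cells$fn) * (cells$tp + cells$fp) +
             (cells$tn + cells$fp) * (cells$tn + cells$fn)) / n^2
      expect_equal(r$sensitivity, st, tolerance = 1e-10)
      expect_equal(r$specificity, sp, tolerance = 1e-10)
      expect_equal(r$geometric_mean, sqrt(st * sp), tolerance = 1e-10)
      expect_equal(r$accuracy, 100 * pa, tolerance = 1e-10)
      if (pe < 1)
        expect_equal(r$kappa, (pa - pe) / (1 - pe), tolerance = 1e-10)
      # structural relations
      expect_lte(r$geometric_mean, max(st, sp) + 1e-10)
      expect_gte(r$geometric_mean, min(st, sp) - 1e-10)
      expect_true(r$kappa_low <= r$kappa && r$kappa <= r$kappa_high)
    }
  })
})

test_that("perfect and chance-level matrices bound the kappa scale", {
  perfect <- score_confusion(list(tp = 10, fn = 0, tn = 10, fp = 0))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$geometric_mean, 100)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$kappa, 1)

  # rows proportional to the column marginals: agreement purely by chance
  chance <- score_confusion(list(tp = 8, fn = 2, fp = 8, tn = 2))
  expect_equal(chance$kappa, 0)
  chance2 <- score_confusion(list(tp = 30, fn = 10, fp = 15, tn = 5))
  expect_equal(chance2$kappa, 0)

  expect_error(score_confusion(list(tp = 0, fn = 0, tn = 0, fp = 0)),
               class = "fhrscreen_input_error")
})

test_that("confusion matrix counts treat at-risk (-1) as positive", {
  truth <- c(-1, -1, -1, 1, 1)
  pred <- c(-1, 1, -1, -1, 1)
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm$tp, 2)
  expect_equal(cm$fn, 1)
  expect_equal(cm$fp, 1)
  expect_equal(cm$tn, 1)
})

test_that("stratified folds preserve the class ratio and partition the data", {
  labels <- c(rep(1, 20), rep(-1, 40))
  folds <- stratified_kfold(labels, k = 5, seed = 3)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f, 12)
    expect_equal(sum(labels[f] == 1), 4)
    expect_equal(sum(labels[f] == -1), 8)
  }
  expect_setequal(unlist(folds), seq_along(labels))
  expect_equal(sum(lengths(folds)), length(labels))

  expect_identical(stratified_kfold(labels, 5, seed = 3), folds)
  expect_false(identical(stratified_kfold(labels, 5, seed = 4), folds))

  expect_error(stratified_kfold(labels, k = 1),
               class = "fhrscreen_input_error")
  expect_error(stratified_kfold(c(1, -1), k = 5),
               class = "fhrscreen_input_error")

  # uneven counts: per-fold class counts within 1 of proportionality
  labels2 <- c(rep(1, 7), rep(-1, 11))
  folds2 <- stratified_kfold(labels2, k = 3, seed = 1)
  for (f in folds2) {
    expect_lte(abs(sum(labels2[f] == 1) - 7 / 3), 1)
    expect_lte(abs(sum(labels2[f] == -1) - 11 / 3), 1)
  }
})

test_that("cross-validation recovers a strongly separated feature set", {
  withr::with_seed(62, {
    x <- rbind(matrix(rnorm(20 * 4, mean = 0), ncol = 4),
               matrix(rnorm(40 * 4, mean = 3), ncol = 4))
  })
  labels <- c(rep(1, 20), rep(-1, 40))
  cv <- cross_validate(x, labels, C = 4, gamma = 2, k = 5, seed = 1)
  expect_gte(cv$cv_accuracy, 85)
  expect_equal(nrow(cv$fold_reports), 5)
  expect_equal(sort(cv$predictions$index), 1:60)

  cv2 <- cross_validate(x, labels, C = 4, gamma = 2, k = 5, seed = 1)
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("shuffled labels drive cross-validation to chance level", {
  withr::with_seed(63, {
    x <- rbind(matrix(rnorm(20 * 4, mean = 0), ncol = 4),
               matrix(rnorm(40 * 4, mean = 3), ncol = 4))
    accs <- vapply(1:10, function(s) {
      y_perm <- sample(c(rep(1, 20), rep(-1, 40)))
      cross_validate(x, y_perm, C = 4, gamma = 2, k = 5,
                     seed = s)$cv_accuracy
    }, 0)
  })
  expect_lte(abs(mean(accs) - 100 * 40 / 60), 2 * sd(accs))
})

test_that("evaluation reports round-trip through key-value text", {
  r <- score_confusion(list(tp = 19, fn = 1, tn = 7, fp = 3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_evaluation(r, path, config = fhr_config())
  back <- read_evaluation(path)
  expect_equal(back$kappa, r$kappa, tolerance = 1e-9)
  expect_equal(back$geometric_mean, r$geometric_mean, tolerance = 1e-9)
  td <- tidy(r)
  expect_equal(td$value[td$metric == "sensitivity"], 95)
})
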