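test_that("RBF kernel has unit diagonal, symmetry and a PSD Gram matrix", {
  withr::with_seed(51, {
    for (i in 1:5) {
      v <- rnorm(4)
      expect_equal(rbf_kernel(v, v, gamma = 2), 1)
    }
  })
  expect_equal(rbf_kernel(0, 1, gamma = 2), exp(-2))
  a <- c(1, 2); b <- c(3, -1)
  expect_equal(rbf_kernel(a, b, 0.7), rbf_kernel(b, a, 0.7))
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1),
               class = "fhrscreen_input_error")

  x <- withr::with_seed(52, matrix(rnorm(20 * 5), ncol = 5))
  G <- fhrscreen:::rbf_gram(x, x, gamma = 2)
  expect_equal(G, t(G))
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # gram matrix agrees with the pairwise kernel
  expect_equal(G[3, 7], rbf_kernel(x[3, ], x[7, ], 2))
})

test_that("min-max scaling maps training data to [-1, 1] and is reusable", {
  x <- withr::with_seed(53, matrix(runif(60, 10, 50), ncol = 3))
  sc <- fit_scaling(x)
  xs <- apply_scaling(sc, x)
  expect_equal(unname(apply(xs, 2, min)), rep(-1, 3))
  expect_equal(unname(apply(xs, 2, max)), rep(1, 3))
  # test data uses the training transform, not its own ranges
  xt <- matrix(c(10, 30, 50, 60, 25, 40), ncol = 3)
  expect_equal(apply_scaling(sc, xt)[1, 1],
               -1 + 2 * (10 - sc$min[1]) / (sc$max[1] - sc$min[1]))
  # degenerate feature maps to the interval midpoint
  xd <- cbind(x[, 1], 7)
  scd <- fit_scaling(xd)
  expect_equal(unname(apply_scaling(scd, xd)[, 2]), rep(0, nrow(xd)))
})

test_that("the weighted SVM separates the toy problem and satisfies the dual", {
  toy <- toy_blobs(10)
  model <- svm_fit(toy$x, toy$y, C = 4, gamma = 2)
  expect_equal(svm_predict(model, toy$x), toy$y)
  # dual constraint sum(alpha_i d_i) = 0
  expect_lt(abs(sum(model$dual_coefs)), 1e-6)
  # box constraints 0 <= alpha_i <= C_class(i)
  w <- model$class_weights
  cap <- ifelse(model$dual_coefs > 0, model$C * w[["1"]],
                model$C * w[["-1"]])
  expect_true(all(abs(model$dual_coefs) <= cap + 1e-8))

  expect_error(svm_fit(toy$x, rep(1, 20)), class = "fhrscreen_input_error")
  expect_error(svm_fit(toy$x, rep(c(0, 1), 10)),
               class = "fhrscreen_input_error")
})

test_that("class weights follow the inverse-cardinality rule", {
  labels <- c(rep(1, 20), rep(-1, 40))
  w <- fhrscreen:::svm_class_weights(labels, "inverse")
  expect_equal(w[["1"]] / w[["-1"]], 2)
  # mirrored imbalance flips the ratio
  w2 <- fhrscreen:::svm_class_weights(-labels, "inverse")
  expect_equal(w2[["1"]] / w2[["-1"]], 0.5)
  expect_null(fhrscreen:::svm_class_weights(labels, NULL))
})

test_that("our decision function reproduces the reference solver's predictions", {
  withr::with_seed(54, {
    x <- rbind(matrix(rnorm(40, 0, 1.5), ncol = 2),
               matrix(rnorm(80, 3, 1.5), ncol = 2))
  })
  y <- c(rep(1, 20), rep(-1, 40))
  model <- svm_fit(x, y, C = 4, gamma = 2)
  xs <- apply_scaling(model$scaling, x)
  ref <- e1071::svm(xs, factor(y, levels = c(1, -1)),
                    type = "C-classification", kernel = "radial", gamma = 2,
                    cost = 4, class.weights = model$class_weights,
                    scale = FALSE)
  expect_equal(svm_predict(model, x),
               as.numeric(as.character(predict(ref, xs))))
  expect_true(all(svm_predict(model, x) %in% c(-1, 1)))
})

test_that("unbounded support vectors sit on the margin", {
  toy <- toy_blobs(15, seed = 55)
  model <- svm_fit(toy$x, toy$y, C = 4, gamma = 0.5)
  dv <- svm_decision(model, toy$x)
  w <- model$class_weights
  cap <- ifelse(model$dual_coefs > 0, model$C * w[["1"]], model$C * w[["-1"]])
  free <- abs(model$dual_coefs) < cap - 1e-6 & abs(model$dual_coefs) > 1e-6
  margins <- abs(dv[model$sv_index[free]])
  expect_true(all(abs(margins - 1) < 1e-2))
})

test_that("duplicating every training point leaves the decision function unchanged", {
  toy <- toy_blobs(10, seed = 56)
  m1 <- svm_fit(toy$x, toy$y, C = 4, gamma = 2)
  m2 <- svm_fit(rbind(toy$x, toy$x), c(toy$y, toy$y), C = 4, gamma = 2)
  grid <- withr::with_seed(57, matrix(rnorm(40, 3, 3), ncol = 2))
  expect_equal(svm_decision(m2, grid), svm_decision(m1, grid),
               tolerance = 0.05)
  expect_equal(svm_predict(m2, toy$x), svm_predict(m1, toy$x))
})

test_that("grid search returns the dominating cell and can refine to (4, 2)", {
  withr::with_seed(58, {
    x <- rbind(matrix(rnorm(30, 0, 1), ncol = 2),
               matrix(rnorm(30, 5, 1), ncol = 2))
  })
  y <- rep(c(1, -1), each = 15)
  # gamma = 500 memorises islands and generalises at chance; the planted
  # sensible cell must win
  gs <- svm_grid_search(x, y, C_grid = c(1), gamma_grid = c(500, 0.5),
                        n_folds = 3, seed = 1, refine = FALSE)
  expect_equal(gs$gamma, 0.5)
  expect_gte(gs$cv_accuracy, 90)

  single <- svm_grid_search(x, y, C_grid = 2, gamma_grid = 0.25,
                            n_folds = 3, seed = 1, refine = FALSE)
  expect_equal(single$C, 2)
  expect_equal(single$gamma, 0.25)

  # half-octave refinement around (2, 2) or (8, 2) reaches the (4, 2) cell
  ref <- svm_grid_search(x, y, C_grid = 2, gamma_grid = 2,
                         n_folds = 3, seed = 1, refine = TRUE)
  expect_true(any(abs(ref$table$C - 4) < 1e-9))
  expect_true(any(abs(ref$table$gamma - 2) < 1e-9))
})

test_that("a saved model reproduces predictions bit-identically", {
  ds <- generate_fhr_dataset(3, 6, seed = 59, duration_s = 300)
  feats <- build_dataset(ds)$features
  model <- svm_fit(feats)
  path <- withr::local_tempfile(fileext = ".json")
  write_svm_model(model, path)
  back <- read_svm_model(path)
  expect_identical(svm_decision(back, feats), svm_decision(model, feats))
  expect_identical(svm_predict(back, feats), svm_predict(model, feats))
})

test_that("tidy and glance summarise a fitted SVM", {
  toy <- toy_blobs(10)
  model <- svm_fit(toy$x, toy$y)
  td <- tidy(model)
  expect_equal(nrow(td), nrow(model$support_vectors))
  g <- glance(model)
  expect_equal(g$C, 4)
  expect_equal(g$gamma, 2)
  expect_equal(g$weight_ratio, 1)  # balanced toy set
  expect_lt(abs(g$dual_sum), 1e-6)
})
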