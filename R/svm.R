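#' Min-max feature scaling to a fixed interval
#'
#' Learns per-feature minima and maxima on the training set and maps each
#' feature linearly onto `[lower, upper]` (default [-1, +1]). The same
#' transform must be applied to training and test data; a degenerate feature
#' (min equal to max) maps to the interval midpoint.
#'
#' @param x numeric matrix (rows = records, columns = features).
#' @param lower,upper target interval endpoints.
#' @return an object of class `fhr_scaling`.
#' @export
fit_scaling <- function(x, lower = -1, upper = 1) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 lower = lower, upper = upper),
            class = "fhr_scaling")
}

#' @rdname fit_scaling
#' @param scaling an `fhr_scaling`.
#' @export
apply_scaling <- function(scaling, x) {
  x <- as.matrix(x)
  stopifnot(inherits(scaling, "fhr_scaling"), ncol(x) == length(scaling$min))
  rng <- scaling$max - scaling$min
  mid <- (scaling$lower + scaling$upper) / 2
  out <- x
  for (j in seq_len(ncol(x))) {
    if (rng[j] == 0) out[, j] <- mid
    else out[, j] <- scaling$lower +
        (x[, j] - scaling$min[j]) / rng[j] * (scaling$upper - scaling$lower)
  }
  out
}

#' Radial basis function kernel
#'
#' `K(a, b) = exp(-gamma * ||a - b||^2)`; 1 at zero distance, decaying with
#' squared Euclidean distance.
#'
#' @param a,b numeric vectors of equal length, or `b` a matrix whose rows are
#'   compared against `a`.
#' @param gamma positive kernel width parameter.
#' @return scalar in (0, 1], or a vector when `b` is a matrix.
#' @examples
#' rbf_kernel(c(0), c(1), gamma = 2)  # exp(-2)
#' @export
rbf_kernel <- function(a, b, gamma) {
  stopifnot(gamma > 0)
  if (is.matrix(b)) {
    if (length(a) != ncol(b))
      rlang::abort("dimension mismatch in rbf_kernel",
                   class = "fhrscreen_input_error")
    return(exp(-gamma * colSums((t(b) - a)^2)))
  }
  if (length(a) != length(b))
    rlang::abort("dimension mismatch in rbf_kernel",
                 class = "fhrscreen_input_error")
  exp(-gamma * sum((a - b)^2))
}

rbf_gram <- function(x, y, gamma) {
  # ||xi - yj||^2 = ||xi||^2 + ||yj||^2 - 2 xi.yj
  xn <- rowSums(x^2)
  yn <- rowSums(y^2)
  d2 <- outer(xn, yn, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit the class-weighted soft-margin RBF SVM
#'
#' Solves the weighted soft-margin dual with per-class box constraints: the
#' penalty ratio C+/C- is set to the inverse ratio of the class cardinalities
#' (n-/n+), so errors on the minority class are penalised more heavily. With
#' the study design of 20 normal and 40 at-risk training records this gives
#' C+/C- = 2. Features are min-max scaled to [-1, +1] internally; the learned
#' transform is stored in the model and re-applied at prediction time.
#'
#' @param features feature tibble (with `sd_*` columns) or numeric matrix.
#' @param labels numeric vector of +1 (normal) / -1 (at risk); both classes
#'   must be present. Taken from a `label` column when absent.
#' @param C base penalty parameter (default 4).
#' @param gamma RBF kernel width (default 2).
#' @param class_weights optional named weights overriding the inverse-
#'   cardinality rule, e.g. `c("1" = 2, "-1" = 1)`; `NULL` disables weighting.
#' @param scale logical: learn and apply min-max scaling (default TRUE).
#' @param tolerance termination tolerance of the quadratic-program solver.
#' @return an object of class `fhr_svm` holding the support vectors, dual
#'   coefficients (alpha_i * d_i), bias, kernel and penalty parameters, and
#'   the scaling transform.
#' @export
svm_fit <- function(features, labels = NULL, C = 4, gamma = 2,
                    class_weights = "inverse", scale = TRUE,
                    tolerance = 1e-3) {
  if (is.null(labels) && is.data.frame(features)) labels <- features$label
  x <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  labels <- as.numeric(labels)
  stopifnot(nrow(x) == length(labels), C > 0, gamma > 0)
  if (!all(labels %in% c(-1, 1)))
    rlang::abort("labels must be +1 or -1", class = "fhrscreen_input_error")
  if (length(unique(labels)) < 2)
    rlang::abort("both classes must be present to fit the SVM",
                 class = "fhrscreen_input_error")
  scaling <- if (scale) fit_scaling(x) else NULL
  xs <- if (scale) apply_scaling(scaling, x) else x
  wts <- svm_class_weights(labels, class_weights)
  y <- factor(labels, levels = c(1, -1))
  fit <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = C, class.weights = wts,
                    scale = FALSE, tolerance = tolerance)
  # orientation: libsvm's decision-value sign follows its internal label
  # order ("a/b" column name: positive votes for a); canonicalise so that
  # positive decision values always mean class +1 (normal)
  sv <- xs[fit$index, , drop = FALSE]
  coefs <- as.numeric(fit$coefs)
  rho <- fit$rho
  dec_attr <- attr(stats::predict(fit, xs, decision.values = TRUE),
                   "decision.values")
  pos_level <- strsplit(colnames(dec_attr)[1], "/")[[1]][1]
  s <- if (pos_level == "1") 1 else -1
  structure(
    list(support_vectors = sv,
         sv_index = fit$index,
         dual_coefs = s * coefs,
         bias = -s * rho,
         gamma = gamma, C = C,
         class_weights = wts,
         n_by_class = table(factor(labels, levels = c(1, -1))),
         scaling = scaling,
         tolerance = tolerance,
         n_features = ncol(x)),
    class = "fhr_svm")
}

svm_class_weights <- function(labels, class_weights) {
  if (is.null(class_weights)) return(NULL)
  if (is.numeric(class_weights)) return(class_weights)
  if (identical(class_weights, "inverse")) {
    n_pos <- sum(labels == 1)
    n_neg <- sum(labels == -1)
    # C+/C- = n-/n+, normalised so the larger class keeps weight 1
    w <- c("1" = n_neg / n_pos, "-1" = 1)
    if (w[["1"]] < 1) w <- w / w[["1"]]
    return(w)
  }
  rlang::abort("class_weights must be NULL, 'inverse', or a named numeric",
               class = "fhrscreen_config_error")
}

#' Decision values and class predictions
#'
#' The decision function is evaluated from the stored support vectors and
#' dual coefficients, `f(x) = sum_i alpha_i d_i K(x_i, x) + b`; the predicted
#' class is its sign, with an exact zero mapped to +1 (normal).
#'
#' @param model an `fhr_svm` from [svm_fit()].
#' @param features feature tibble or numeric matrix on the original (unscaled)
#'   scale; the model's stored transform is applied.
#' @return `svm_decision()`: numeric decision values; `svm_predict()`: a
#'   vector of +1 / -1.
#' @export
svm_decision <- function(model, features) {
  stopifnot(inherits(model, "fhr_svm"))
  x <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  if (ncol(x) != model$n_features)
    rlang::abort("feature dimension does not match the model",
                 class = "fhrscreen_input_error")
  xs <- if (!is.null(model$scaling)) apply_scaling(model$scaling, x) else x
  # new data may overshoot the training min-max a little; warn only when it
  # lands far outside, which points at input on the wrong scale
  if (!is.null(model$scaling)) {
    width <- model$scaling$upper - model$scaling$lower
    if (any(xs < model$scaling$lower - 3 * width |
            xs > model$scaling$upper + 3 * width))
      rlang::warn("features fall far outside the training range; is the input on the model's scale?")
  }
  as.numeric(rbf_gram(xs, model$support_vectors, model$gamma) %*%
               model$dual_coefs) + model$bias
}

#' @rdname svm_decision
#' @export
svm_predict <- function(model, features) {
  dv <- svm_decision(model, features)
  ifelse(dv >= 0, 1, -1)
}

#' Grid search for the penalty and kernel-width parameters
#'
#' Two-stage search driven by stratified cross-validation accuracy: a coarse
#' pass over exponentially spaced grids (defaults 2^-5..2^15 for C and
#' 2^-15..2^3 for gamma, in octave steps), then a refinement pass at
#' half-octave steps around the best coarse cell. Ties are broken towards
#' smaller C, then smaller gamma.
#'
#' @inheritParams svm_fit
#' @param C_grid,gamma_grid coarse grids (positive numeric vectors).
#' @param n_folds stratified CV folds (default 5).
#' @param seed fold-assignment seed.
#' @param refine logical: run the half-octave refinement pass.
#' @return list with `C`, `gamma`, `cv_accuracy` (percent), and `table`, a
#'   tibble of every cell evaluated (`C`, `gamma`, `cv_accuracy`, `stage`).
#' @export
svm_grid_search <- function(features, labels = NULL,
                            C_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            n_folds = 5, seed = 1,
                            class_weights = "inverse", refine = TRUE) {
  if (is.null(labels) && is.data.frame(features)) labels <- features$label
  x <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  stopifnot(length(C_grid) >= 1, length(gamma_grid) >= 1, n_folds >= 2)
  eval_grid <- function(Cs, gs, stage) {
    cells <- expand.grid(C = Cs, gamma = gs, KEEP.OUT.ATTRS = FALSE)
    cells$cv_accuracy <- vapply(seq_len(nrow(cells)), function(i) {
      cross_validate(x, labels, C = cells$C[i], gamma = cells$gamma[i],
                     k = n_folds, seed = seed,
                     class_weights = class_weights)$cv_accuracy
    }, 0)
    cells$stage <- stage
    cells
  }
  tab <- eval_grid(C_grid, gamma_grid, "coarse")
  best <- pick_best_cell(tab)
  if (refine) {
    Cs <- best$C * 2^seq(-1, 1, by = 0.5)
    gs <- best$gamma * 2^seq(-1, 1, by = 0.5)
    tab2 <- eval_grid(Cs, gs, "refine")
    tab <- rbind(tab, tab2)
    best <- pick_best_cell(tab)
  }
  list(C = best$C, gamma = best$gamma, cv_accuracy = best$cv_accuracy,
       table = tibble::as_tibble(tab))
}

pick_best_cell <- function(tab) {
  ord <- order(-tab$cv_accuracy, tab$C, tab$gamma)
  tab[ord[1], ]
}

#' @export
print.fhr_svm <- function(x, ...) {
  cat(sprintf("<fhr_svm> RBF SVM: %d support vectors, C = %g, gamma = %g, C+/C- = %g\n",
              nrow(x$support_vectors), x$C, x$gamma,
              if (is.null(x$class_weights)) 1
              else x$class_weights[["1"]] / x$class_weights[["-1"]]))
  invisible(x)
}

#' Save / load a fitted SVM as structured text
#'
#' JSON with all doubles written as full-precision "%.17g" strings, so a
#' round-trip reproduces predictions bit-identically.
#'
#' @param model an `fhr_svm`.
#' @param path file path.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "fhr_svm"))
  num <- function(v) sprintf("%.17g", as.numeric(v))
  payload <- list(
    format = "fhrscreen_svm_v1",
    n_features = model$n_features,
    sv_index = model$sv_index,
    support_vectors = apply(model$support_vectors, 1, num, simplify = FALSE),
    dual_coefs = num(model$dual_coefs),
    bias = num(model$bias),
    gamma = num(model$gamma),
    C = num(model$C),
    class_weights = if (is.null(model$class_weights)) NULL
      else as.list(stats::setNames(num(model$class_weights),
                                   names(model$class_weights))),
    n_by_class = as.list(model$n_by_class),
    scaling = if (is.null(model$scaling)) NULL else list(
      min = num(model$scaling$min), max = num(model$scaling$max),
      lower = num(model$scaling$lower), upper = num(model$scaling$upper)),
    tolerance = num(model$tolerance))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  p <- jsonlite::read_json(path)
  if (!identical(p$format, "fhrscreen_svm_v1"))
    rlang::abort("not an fhrscreen SVM model file",
                 class = "fhrscreen_input_error")
  num <- function(v) as.numeric(unlist(v))
  sv <- do.call(rbind, lapply(p$support_vectors, num))
  scaling <- if (is.null(p$scaling)) NULL else
    structure(list(min = num(p$scaling$min), max = num(p$scaling$max),
                   lower = num(p$scaling$lower), upper = num(p$scaling$upper)),
              class = "fhr_scaling")
  structure(
    list(support_vectors = sv,
         sv_index = as.integer(unlist(p$sv_index)),
         dual_coefs = num(p$dual_coefs),
         bias = num(p$bias),
         gamma = num(p$gamma), C = num(p$C),
         class_weights = if (is.null(p$class_weights)) NULL
           else stats::setNames(num(p$class_weights), names(p$class_weights)),
         n_by_class = unlist(p$n_by_class),
         scaling = scaling,
         tolerance = num(p$tolerance),
         n_features = as.integer(p$n_features)),
    class = "fhr_svm")
}
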