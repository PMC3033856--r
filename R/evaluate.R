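#' Build a confusion matrix with 'at risk' as the positive class
#'
#' The screening question is "does this trace need attention", so the at-risk
#' label (-1) is the positive class: `tp` counts at-risk traces called
#' at-risk, `tn` normal traces called normal.
#'
#' @param truth,predicted numeric vectors of +1 (normal) / -1 (at risk).
#' @return one-row tibble with integer columns `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tibble::tibble(
    tp = sum(truth == -1 & predicted == -1),
    fn = sum(truth == -1 & predicted == 1),
    tn = sum(truth == 1 & predicted == 1),
    fp = sum(truth == 1 & predicted == -1))
}

#' Score a confusion matrix
#'
#' Sensitivity `S_T = tp/(tp+fn)`, specificity `S_P = tn/(tn+fp)`, their
#' geometric mean `G_M = sqrt(S_T * S_P)` (the imbalance-robust summary),
#' accuracy, and Cohen's kappa `k = (p_a - p_e)/(1 - p_e)` with its 95%
#' confidence interval from the large-sample standard error
#' `sqrt(p_a (1 - p_a) / (n (1 - p_e)^2))`. Rates are reported in percent.
#'
#' @param confusion one-row tibble or named list/vector with `tp`, `fn`,
#'   `tn`, `fp`.
#' @return an `fhr_evaluation`: a one-row tibble with columns `tp`, `fn`,
#'   `tn`, `fp`, `sensitivity`, `specificity`, `geometric_mean`, `accuracy`
#'   (percent), `kappa`, `kappa_low`, `kappa_high`, `p_a`, `p_e`.
#' @examples
#' score_confusion(list(tp = 40, fn = 0, tn = 18, fp = 2))
#' @export
score_confusion <- function(confusion) {
  cm <- as.list(confusion)
  tp <- as.numeric(cm$tp); fn <- as.numeric(cm$fn)
  tn <- as.numeric(cm$tn); fp <- as.numeric(cm$fp)
  stopifnot(all(c(tp, fn, tn, fp) >= 0))
  n <- tp + fn + tn + fp
  if (n == 0)
    rlang::abort("empty confusion matrix", class = "fhrscreen_input_error")
  st <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  gm <- sqrt(st * sp)
  acc <- 100 * (tp + tn) / n
  p_a <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (p_e < 1) (p_a - p_e) / (1 - p_e) else NA_real_
  se <- if (p_e < 1) sqrt(p_a * (1 - p_a) / (n * (1 - p_e)^2)) else NA_real_
  out <- tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = st, specificity = sp, geometric_mean = gm,
    accuracy = acc, kappa = kappa,
    kappa_low = kappa - stats::qnorm(0.975) * se,
    kappa_high = kappa + stats::qnorm(0.975) * se,
    p_a = p_a, p_e = p_e)
  class(out) <- c("fhr_evaluation", class(out))
  out
}

#' @rdname score_confusion
#' @param truth,predicted label vectors, an alternative entry point.
#' @export
evaluate_predictions <- function(truth, predicted) {
  score_confusion(confusion_matrix(truth, predicted))
}

#' Stratified k-fold assignment
#'
#' Partitions indices into k folds with per-class counts within one of exact
#' proportionality, deterministically for a given seed. With the study design
#' of 20 normal / 40 at-risk records and k = 5, every fold holds 12 records:
#' 4 normal and 8 at-risk.
#'
#' @param labels numeric vector of +1 / -1 (any discrete labels work).
#' @param k number of folds (at least 2, at most `length(labels)`).
#' @param seed integer seed for the shuffle.
#' @return list of k integer index vectors, jointly a partition of
#'   `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1) {
  n <- length(labels)
  if (k < 2) rlang::abort("k must be at least 2",
                          class = "fhrscreen_input_error")
  if (k > n) rlang::abort("more folds than records",
                          class = "fhrscreen_input_error")
  folds <- vector("list", k)
  rng <- local_rng(seed)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[order(rng(length(idx)))]
    assign_to <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
  }
  lapply(folds, sort)
}

# seeded uniform draws that do not disturb the global RNG stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, envir = globalenv())
    out <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    out
  }
}

#' Stratified k-fold cross-validation of the weighted SVM
#'
#' For each fold: the min-max scaling and the inverse-cardinality class
#' weights are recomputed on the training portion, the SVM is fitted there,
#' and the held-out fold is predicted. The CV accuracy pools correct
#' predictions over all folds.
#'
#' @inheritParams svm_fit
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `cv_accuracy` (percent, pooled), `pooled` (an
#'   `fhr_evaluation` over all held-out predictions), `fold_reports` (tibble
#'   of per-fold evaluations), and `predictions` (tibble: `index`, `fold`,
#'   `truth`, `predicted`).
#' @export
cross_validate <- function(features, labels = NULL, C = 4, gamma = 2,
                           k = 5, seed = 1, class_weights = "inverse") {
  if (is.null(labels) && is.data.frame(features)) labels <- features$label
  x <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  labels <- as.numeric(labels)
  folds <- stratified_kfold(labels, k = k, seed = seed)
  preds <- numeric(length(labels))
  fold_of <- integer(length(labels))
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    model <- svm_fit(x[train_idx, , drop = FALSE], labels[train_idx],
                     C = C, gamma = gamma, class_weights = class_weights)
    preds[test_idx] <- svm_predict(model, x[test_idx, , drop = FALSE])
    fold_of[test_idx] <- f
    fold_reports[[f]] <- dplyr::mutate(
      evaluate_predictions(labels[test_idx], preds[test_idx]),
      fold = f, .before = 1)
  }
  pooled <- evaluate_predictions(labels, preds)
  list(cv_accuracy = pooled$accuracy,
       pooled = pooled,
       fold_reports = dplyr::bind_rows(fold_reports),
       predictions = tibble::tibble(index = seq_along(labels),
                                    fold = fold_of, truth = labels,
                                    predicted = preds))
}

#' Train-set / test-set evaluation, the study protocol
#'
#' Fits the weighted SVM on the training table (with its k-fold CV accuracy)
#' and scores both the training and the held-out testing tables.
#'
#' @param train,test feature tibbles with `label` columns.
#' @inheritParams cross_validate
#' @return list with `model`, `cv` (from [cross_validate()]), `train_eval`
#'   and `test_eval` (both `fhr_evaluation`).
#' @export
evaluate_split <- function(train, test, C = 4, gamma = 2, k = 5, seed = 1,
                           class_weights = "inverse") {
  if (!nrow(train) || !nrow(test))
    rlang::abort("empty feature table", class = "fhrscreen_input_error")
  model <- svm_fit(train, C = C, gamma = gamma, class_weights = class_weights)
  cv <- cross_validate(train, C = C, gamma = gamma, k = k, seed = seed,
                       class_weights = class_weights)
  train_eval <- evaluate_predictions(train$label, svm_predict(model, train))
  test_eval <- evaluate_predictions(test$label, svm_predict(model, test))
  list(model = model, cv = cv, train_eval = train_eval,
       test_eval = test_eval)
}

#' @export
print.fhr_evaluation <- function(x, ...) {
  cat("<fhr_evaluation> rows = expert label, cols = SVM output ('at risk' positive)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("at risk", "normal"),
                              c("at risk", "normal")))
  print(m)
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  G_M %.2f  accuracy %.2f%%\n",
              x$sensitivity, x$specificity, x$geometric_mean, x$accuracy))
  cat(sprintf("kappa %.3f (95%% CI %.3f to %.3f)\n",
              x$kappa, x$kappa_low, x$kappa_high))
  invisible(x)
}

#' Write an evaluation report as key-value text
#'
#' @param report an `fhr_evaluation`.
#' @param path file path.
#' @param config optional list embedded as `#`-comment header lines.
#' @export
write_evaluation <- function(report, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  for (nm in names(report))
    writeLines(sprintf("%s: %.10g", nm, report[[nm]]), con)
  invisible(path)
}

#' @rdname write_evaluation
#' @export
read_evaluation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  kv <- strsplit(lines, ":\\s*")
  out <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                         vapply(kv, `[`, "", 1))
  out <- tibble::as_tibble(out)
  class(out) <- c("fhr_evaluation", class(out))
  out
}
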