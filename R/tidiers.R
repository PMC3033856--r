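#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns one row per elementary unit
#' (component, support vector, or metric), `glance()` a one-row model
#' summary.
#'
#' @param x an `emd_decomposition`, `fhr_svm`, or `fhr_evaluation`.
#' @param ... unused.
#' @return a tibble.
#' @name fhrscreen-tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname fhrscreen-tidiers
#' @export
tidy.emd_decomposition <- function(x, ...) {
  m <- emd_components(x)
  n <- nrow(m)
  time_s <- if (is.finite(x$fs)) (seq_len(n) - 1) / x$fs else seq_len(n) - 1
  tibble::tibble(
    time_s = rep(time_s, ncol(m)),
    component = factor(rep(colnames(m), each = n), levels = colnames(m)),
    value = as.vector(m))
}

#' @rdname fhrscreen-tidiers
#' @export
glance.emd_decomposition <- function(x, ...) {
  recon <- emd_reconstruct(x)
  tibble::tibble(
    n_imfs = n_imfs(x),
    n_imfs_total = x$n_imfs_total,
    sifting_threshold = x$sifting_threshold,
    max_reconstruction_error = max(abs(x$signal - recon)))
}

#' @rdname fhrscreen-tidiers
#' @export
tidy.fhr_svm <- function(x, ...) {
  sv <- tibble::as_tibble(x$support_vectors, .name_repair = "minimal")
  names(sv) <- paste0("sv_", seq_len(ncol(sv)))
  dplyr::mutate(sv, dual_coef = x$dual_coefs, .before = 1)
}

#' @rdname fhrscreen-tidiers
#' @export
glance.fhr_svm <- function(x, ...) {
  tibble::tibble(
    n_support_vectors = nrow(x$support_vectors),
    C = x$C, gamma = x$gamma,
    weight_ratio = if (is.null(x$class_weights)) 1
      else unname(x$class_weights[["1"]] / x$class_weights[["-1"]]),
    bias = x$bias,
    dual_sum = sum(x$dual_coefs))
}

#' @rdname fhrscreen-tidiers
#' @export
tidy.fhr_evaluation <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity", "geometric_mean", "accuracy",
               "kappa"),
    value = c(x$sensitivity, x$specificity, x$geometric_mean, x$accuracy,
              x$kappa))
}

#' @rdname fhrscreen-tidiers
#' @export
glance.fhr_evaluation <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
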