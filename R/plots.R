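#' Plot methods
#'
#' `ggplot2::autoplot()` methods for the package's result types: a trace
#' (bpm against time, dropouts blanked), a decomposition (one facet per
#' component), and an evaluation (confusion-matrix tile plot annotated with
#' the headline rates).
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return a ggplot.
#' @name fhrscreen-plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname fhrscreen-plots
#' @export
autoplot.fhr_trace <- function(object, ...) {
  df <- tibble::tibble(time_s = object$time_s,
                       fhr_bpm = ifelse(object$fhr_bpm == 0, NA_real_,
                                        object$fhr_bpm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$fhr_bpm)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "FHR (bpm)", title = fhr_id(object)) +
    ggplot2::theme_minimal()
}

#' @rdname fhrscreen-plots
#' @export
autoplot.emd_decomposition <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = if (is.finite(object$fs)) "time (s)" else "sample",
                  y = "bpm", title = object$id) +
    ggplot2::theme_minimal()
}

#' @rdname fhrscreen-plots
#' @export
autoplot.fhr_evaluation <- function(object, ...) {
  df <- tibble::tibble(
    truth = factor(c("at risk", "at risk", "normal", "normal"),
                   levels = c("at risk", "normal")),
    predicted = factor(c("at risk", "normal", "at risk", "normal"),
                       levels = c("at risk", "normal")),
    count = c(object$tp, object$fn, object$fp, object$tn))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = "SVM output", y = "expert label",
      title = sprintf("S_T %.1f%%, S_P %.1f%%, G_M %.2f, kappa %.3f",
                      object$sensitivity, object$specificity,
                      object$geometric_mean, object$kappa)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
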