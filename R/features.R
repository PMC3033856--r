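#' Standard deviation of one decomposed component
#'
#' The sample standard deviation with the N-1 denominator,
#' `sqrt(sum((c - mean(c))^2) / (N - 1))`.
#'
#' @param component numeric vector, length at least 2.
#' @return non-negative scalar (bpm for FHR components).
#' @export
component_sd <- function(component) {
  component <- as.numeric(component)
  if (length(component) < 2)
    rlang::abort("component needs at least 2 samples",
                 class = "fhrscreen_input_error")
  stats::sd(component)
}

#' Assemble the IMF standard-deviation feature vector
#'
#' One feature per retained component (fast to slow, residue last), up to the
#' fixed width of 10. Slot k always means "the k-th component retained after
#' the noise-order cut", so slots line up across records even when the noise
#' order differs. Because the number of retained components varies from trace
#' to trace, trailing slots are filled with `pad` (default 0, which scales to
#' the interval midpoint-neutral value after min-max scaling); components
#' beyond the 10th are dropped from the slow tail.
#'
#' @param retained matrix of retained components (columns fast to slow), as
#'   from [denoise()], or a list of numeric vectors.
#' @param label optional class label: +1 (normal), -1 (at risk).
#' @param pad fill value for empty slots; `NA` gives mean-fill downstream.
#' @param n_features fixed feature-vector width (default 10).
#' @return one-row tibble with `sd_1..sd_10`, `n_components`, `label`.
#' @export
extract_features <- function(retained, label = NA_real_, pad = 0,
                             n_features = 10L) {
  if (is.list(retained) && !is.data.frame(retained))
    retained <- do.call(cbind, retained)
  if (is.null(dim(retained))) retained <- matrix(retained, ncol = 1)
  k <- ncol(retained)
  if (k < 1)
    rlang::abort("no retained components to extract features from",
                 class = "fhrscreen_input_error")
  k_used <- min(k, n_features)
  sds <- rep(pad, n_features)
  sds[seq_len(k_used)] <- vapply(seq_len(k_used),
                                 function(j) component_sd(retained[, j]), 0)
  out <- tibble::as_tibble(as.list(stats::setNames(sds, paste0("sd_", seq_len(n_features)))))
  out$n_components <- k_used
  out$label <- label
  out
}

#' Run the full feature-extraction chain over a trace collection
#'
#' For each trace: spike correction, missing-beat removal, EMD, noise-order
#' estimation, denoising, and IMF standard-deviation features. Unusable
#' traces (missing fraction above the cutoff) are excluded, with the reason
#' recorded.
#'
#' @param traces a dataset tibble as produced by [generate_fhr_dataset()]
#'   (columns `id`, `label`, `trace`), or a plain list of [fhr_trace()]
#'   objects with `labels` supplied separately.
#' @param labels optional numeric labels (+1/-1) when `traces` is a list.
#' @param config a [fhr_config()] list controlling every stage.
#' @return list with `features` (tibble, one row per usable trace, columns
#'   `id`, `sd_1..sd_10`, `n_components`, `label`), `excluded` (tibble of
#'   dropped traces and reasons), and `reports` (per-trace cleaning reports).
#' @export
build_dataset <- function(traces, labels = NULL, config = fhr_config()) {
  if (is.data.frame(traces)) {
    ids <- traces$id
    labels <- traces$label
    trace_list <- traces$trace
  } else {
    trace_list <- traces
    ids <- vapply(trace_list, fhr_id, "")
    if (is.null(labels)) labels <- rep(NA_real_, length(trace_list))
  }
  rows <- vector("list", length(trace_list))
  reports <- vector("list", length(trace_list))
  excluded <- list()
  for (i in seq_along(trace_list)) {
    cl <- clean_fhr(trace_list[[i]],
                    jump_bpm = config$preprocess$jump_bpm,
                    bpm_range = config$preprocess$bpm_range,
                    max_missing = config$preprocess$max_missing,
                    interp_max_s = config$preprocess$interp_max_s)
    reports[[i]] <- dplyr::mutate(cl$report, id = ids[[i]], .before = 1)
    if (!cl$report$usable) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        id = ids[[i]],
        reason = sprintf("missing fraction %.2f exceeds cutoff %.2f",
                         cl$report$fraction_missing,
                         config$preprocess$max_missing))
      rows[[i]] <- NULL
      next
    }
    dec <- emd(cl$trace, threshold = config$emd$threshold,
               max_imfs = config$emd$max_imfs,
               max_iter = config$emd$max_iter)
    ord <- estimate_noise_order(dec, alpha = config$preprocess$alpha)
    den <- denoise(dec, ord)
    rows[[i]] <- dplyr::mutate(
      extract_features(den$retained, label = labels[[i]],
                       pad = config$features$pad),
      id = ids[[i]], .before = 1)
  }
  features <- dplyr::bind_rows(rows)
  list(features = features,
       excluded = dplyr::bind_rows(excluded),
       reports = dplyr::bind_rows(reports))
}

#' Write / read a feature table
#'
#' Delimited text with columns `sd_1..sd_10,n_components,label` (plus an `id`
#' column when present); the label column may be absent for prediction
#' inputs.
#'
#' @param features feature tibble, as from [build_dataset()].
#' @param path file path.
#' @param config optional list embedded as `#`-comment header lines.
#' @export
write_feature_table <- function(features, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(features, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- paste0("sd_", 1:10)
  if (!all(need %in% names(df)))
    rlang::abort("feature table lacks sd_1..sd_10 columns",
                 class = "fhrscreen_input_error")
  tibble::as_tibble(df)
}

feature_matrix <- function(features, n_features = 10L) {
  as.matrix(features[paste0("sd_", seq_len(n_features))])
}
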