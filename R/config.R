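#' Pipeline configuration
#'
#' One nested list controlling every stage, serialisable to YAML. All
#' randomness (fold assignment, synthetic generation) flows from the single
#' top-level `seed`.
#'
#' @param emd sifting threshold, IMF cap (`NULL` = `floor(log2(n))`),
#'   iteration cap.
#' @param preprocess t-test significance level, valid bpm band, spike
#'   threshold, usability cutoff on the missing fraction, interpolation
#'   window.
#' @param features pad value for empty feature slots.
#' @param svm penalty `C`, kernel width `gamma`, class weighting mode.
#' @param eval number of CV folds.
#' @param seed top-level seed.
#' @return a named list of class `fhr_config`.
#' @export
fhr_config <- function(emd = list(), preprocess = list(), features = list(),
                       svm = list(), eval = list(), seed = 1) {
  defaults <- list(
    emd = list(threshold = 0.2, max_imfs = NULL, max_iter = 100),
    preprocess = list(alpha = 0.05, bpm_range = c(50, 220), jump_bpm = 25,
                      max_missing = 0.4, interp_max_s = 0),
    features = list(pad = 0),
    svm = list(C = 4, gamma = 2, class_weights = "inverse"),
    eval = list(k = 5),
    seed = seed)
  for (sec in c("emd", "preprocess", "features", "svm", "eval")) {
    user <- get(sec)
    for (nm in names(user)) defaults[[sec]][[nm]] <- user[[nm]]
  }
  structure(defaults, class = c("fhr_config", "list"))
}

#' @rdname fhr_config
#' @param path YAML file path.
#' @export
read_fhr_config <- function(path) {
  if (!file.exists(path))
    rlang::abort(paste0("config file not found: ", path),
                 class = "fhrscreen_config_error")
  raw <- yaml::read_yaml(path)
  if (!is.list(raw))
    rlang::abort("config file is not a YAML mapping",
                 class = "fhrscreen_config_error")
  do.call(fhr_config, raw[intersect(names(raw),
                                    c("emd", "preprocess", "features",
                                      "svm", "eval", "seed"))])
}

#' @rdname fhr_config
#' @param config an `fhr_config`.
#' @export
write_fhr_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# "#"-prefixed header lines embedding the effective config in text artifacts
config_header <- function(config) {
  if (is.null(config)) return(character(0))
  paste0("# config: ",
         strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]])
}

#' Run the full screening pipeline on a trace collection
#'
#' Cleaning, decomposition, denoising and feature extraction
#' ([build_dataset()]) followed by stratified k-fold cross-validation of the
#' class-weighted SVM at the configured operating point.
#'
#' @param traces dataset tibble (see [build_dataset()]).
#' @param config an [fhr_config()].
#' @return list with `features`, `excluded`, `reports` (from
#'   [build_dataset()]) and `cv` (from [cross_validate()]).
#' @export
fhr_pipeline <- function(traces, config = fhr_config()) {
  ds <- build_dataset(traces, config = config)
  if (!nrow(ds$features))
    rlang::abort("no usable traces", class = "fhrscreen_input_error")
  cv <- cross_validate(ds$features, C = config$svm$C,
                       gamma = config$svm$gamma, k = config$eval$k,
                       seed = config$seed,
                       class_weights = config$svm$class_weights)
  c(ds, list(cv = cv, config = config))
}
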