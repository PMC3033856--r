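# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for one synthetic FHR trace
#'
#' The generator emulates the structure of antepartum cardiotocography
#' heart-rate records as the screening method assumes them: a baseline in the
#' normal fetal range, band-limited beat-to-beat variability, smooth
#' bell-shaped accelerations or decelerations, occasional single-sample spike
#' artifacts, and zeroed dropout runs from transducer displacement.
#'
#' Class presets follow clinical convention: a normal trace carries
#' accelerations and healthy variability (at least 5 bpm); an at-risk trace
#' has its variability scaled down (0.4x at `effect_size = 1`) and carries
#' decelerations instead. `effect_size` interpolates the at-risk preset
#' between "identical to normal" (0) and the full pattern (1).
#'
#' @param class_label +1 (normal) or -1 (at risk).
#' @param effect_size class-separation dial in `[0, 1]`.
#' @param duration_s record length in seconds (default 1200: 20 minutes).
#' @param fs sampling rate in Hz (4, the cardiotocograph output rate).
#' @param seed integer seed; every random element of the trace flows from it.
#' @param baseline_bpm,variability_bpm,n_accelerations,n_decelerations,accel_height_bpm,decel_depth_bpm,event_duration_s,spike_rate_per_min,missing_fraction
#'   overrides for individual preset draws.
#' @return a named list of generator parameters (class `fhr_gen_config`).
#' @export
fhr_gen_config <- function(class_label = 1, effect_size = 1,
                           duration_s = 1200, fs = 4, seed = 1,
                           baseline_bpm = NULL, variability_bpm = NULL,
                           n_accelerations = NULL, n_decelerations = NULL,
                           accel_height_bpm = NULL, decel_depth_bpm = NULL,
                           event_duration_s = NULL, spike_rate_per_min = NULL,
                           missing_fraction = NULL) {
  stopifnot(class_label %in% c(-1, 1), effect_size >= 0, effect_size <= 1,
            duration_s > 0, fs > 0)
  draws <- with_seed_local(seed, {
    base_var <- runif(1, 6, 10)
    base_accel <- sample(2:5, 1)
    list(
      baseline_bpm = runif(1, 120, 150),
      variability_bpm = if (class_label == 1) base_var
                        else base_var * (1 - 0.6 * effect_size),
      n_accelerations = if (class_label == 1) base_accel
                        else round((1 - effect_size) * base_accel),
      n_decelerations = if (class_label == 1) 0L
                        else round(effect_size * sample(2:4, 1)),
      accel_height_bpm = runif(1, 12, 20),
      decel_depth_bpm = runif(1, 15, 30),
      event_duration_s = runif(1, 30, 60),
      spike_rate_per_min = 0.5,
      missing_fraction = runif(1, 0.05, 0.15))
  })
  override <- list(baseline_bpm = baseline_bpm,
                   variability_bpm = variability_bpm,
                   n_accelerations = n_accelerations,
                   n_decelerations = n_decelerations,
                   accel_height_bpm = accel_height_bpm,
                   decel_depth_bpm = decel_depth_bpm,
                   event_duration_s = event_duration_s,
                   spike_rate_per_min = spike_rate_per_min,
                   missing_fraction = missing_fraction)
  for (nm in names(override))
    if (!is.null(override[[nm]])) draws[[nm]] <- override[[nm]]
  stopifnot(draws$missing_fraction >= 0, draws$missing_fraction <= 0.45)
  structure(c(list(class_label = class_label, effect_size = effect_size,
                   duration_s = duration_s, fs = fs, seed = seed), draws),
            class = "fhr_gen_config")
}

#' Generate one synthetic FHR trace
#'
#' Builds `baseline + variability + events`, then injects spike artifacts and
#' zeroed dropout runs. Variability is band-limited random-phase harmonic
#' noise (40 sinusoids with frequencies in 0.03-1 Hz) scaled so its standard
#' deviation is `variability_bpm / 2`, i.e. a peak-to-peak spread of roughly
#' `variability_bpm`. All non-dropout samples stay within [50, 220] bpm.
#'
#' @param config an [fhr_gen_config()].
#' @return an [fhr_trace()] with attributes `events` (ground-truth tibble of
#'   injected events, spikes and dropout runs) and `config`.
#' @export
generate_fhr_trace <- function(config) {
  stopifnot(inherits(config, "fhr_gen_config"))
  with_seed_local(config$seed + 104729L, {
    n <- round(config$duration_s * config$fs)
    t <- (seq_len(n) - 1) / config$fs
    events <- list()

    # dense fixed frequency grid with random phases: every trace carries the
    # same red-tilted band-energy profile, so variability_bpm genuinely sets
    # the amplitude of each oscillatory band rather than a random subset
    freqs <- seq(0.03, 1, length.out = 200)
    phases <- runif(200, 0, 2 * pi)
    amps <- 1 / sqrt(freqs)
    v <- colSums(amps * sin(2 * pi * outer(freqs, t) + phases))
    v <- v / stats::sd(v) * config$variability_bpm / 2
    v <- pmin(pmax(v, -2.9 * config$variability_bpm),
              2.9 * config$variability_bpm)
    x <- config$baseline_bpm + v

    add_events <- function(x, n_ev, sign, mag, type) {
      for (i in seq_len(n_ev)) {
        centre <- runif(1, 0.05, 0.95) * config$duration_s
        width <- config$event_duration_s * runif(1, 0.8, 1.2) / 4  # gaussian sd
        height <- mag * runif(1, 0.8, 1.2)
        x <- x + sign * height * exp(-(t - centre)^2 / (2 * width^2))
        events[[length(events) + 1L]] <<- tibble::tibble(
          type = type, start_s = centre - 2 * width,
          duration_s = 4 * width, magnitude_bpm = sign * height)
      }
      x
    }
    x <- add_events(x, config$n_accelerations, 1, config$accel_height_bpm,
                    "acceleration")
    x <- add_events(x, config$n_decelerations, -1, config$decel_depth_bpm,
                    "deceleration")

    n_spikes <- stats::rpois(1, config$spike_rate_per_min *
                                  config$duration_s / 60)
    if (n_spikes > 0) {
      pos <- sample(2:(n - 1), n_spikes)
      jump <- sample(c(-1, 1), n_spikes, replace = TRUE) * runif(n_spikes, 30, 60)
      x[pos] <- x[pos] + jump
      for (i in seq_len(n_spikes))
        events[[length(events) + 1L]] <- tibble::tibble(
          type = "spike", start_s = t[pos[i]], duration_s = 1 / config$fs,
          magnitude_bpm = jump[i])
    }
    x <- pmin(pmax(x, 50), 220)

    target <- round(config$missing_fraction * n)
    missing <- logical(n)
    placed <- 0L
    attempts <- 0L
    while (placed < target && attempts < 20000L) {
      attempts <- attempts + 1L
      len <- min(sample(8:120, 1), target - placed)
      start <- sample.int(n - len + 1L, 1)
      idx <- start:(start + len - 1L)
      if (any(missing[idx])) next
      missing[idx] <- TRUE
      placed <- placed + len
      events[[length(events) + 1L]] <- tibble::tibble(
        type = "dropout", start_s = t[start], duration_s = len / config$fs,
        magnitude_bpm = NA_real_)
    }
    x[missing] <- 0

    tr <- fhr_trace(x, fs = config$fs,
                    id = sprintf("synthetic_%s_%d",
                                 if (config$class_label == 1) "normal" else "atrisk",
                                 config$seed))
    attr(tr, "events") <- dplyr::bind_rows(events)
    attr(tr, "config") <- config
    tr
  })
}

#' Generate a labelled synthetic dataset
#'
#' Per-trace configurations are drawn from the class presets; the default
#' class sizes mirror the study design of 20 normal and 40 at-risk training
#' records (a 1:2 ratio).
#'
#' @param n_normal,n_atrisk class sizes.
#' @param effect_size class-separation dial passed to [fhr_gen_config()].
#' @param seed master seed; per-trace seeds are derived from it.
#' @param duration_s,fs record length and sampling rate.
#' @param ... further overrides forwarded to [fhr_gen_config()].
#' @return tibble with columns `id`, `label` (+1/-1), `seed`, `trace`
#'   (list-column of [fhr_trace()]), `events` (list-column of ground truth).
#' @export
generate_fhr_dataset <- function(n_normal = 20, n_atrisk = 40,
                                 effect_size = 1, seed = 1,
                                 duration_s = 1200, fs = 4, ...) {
  stopifnot(n_normal >= 1, n_atrisk >= 1)
  n <- n_normal + n_atrisk
  trace_seeds <- with_seed_local(seed, sample.int(2147483646L, n))
  labels <- c(rep(1, n_normal), rep(-1, n_atrisk))
  rows <- lapply(seq_len(n), function(i) {
    cfg <- fhr_gen_config(class_label = labels[i], effect_size = effect_size,
                          duration_s = duration_s, fs = fs,
                          seed = trace_seeds[i], ...)
    tr <- generate_fhr_trace(cfg)
    tibble::tibble(id = fhr_id(tr), label = labels[i], seed = trace_seeds[i],
                   trace = list(tr), events = list(attr(tr, "events")))
  })
  out <- dplyr::bind_rows(rows)
  out$id <- make.unique(out$id, sep = "_r")
  out
}

#' Write a dataset of traces plus a manifest
#'
#' Each trace goes to `<dir>/<id>.csv` in the two-column trace format; the
#' manifest (`manifest.csv`) records id, label, seed and file name.
#'
#' @param dataset tibble from [generate_fhr_dataset()].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_fhr_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    files[i] <- paste0(dataset$id[i], ".csv")
    write_fhr_trace(dataset$trace[[i]], file.path(dir, files[i]))
  }
  manifest <- tibble::tibble(id = dataset$id, label = dataset$label,
                             seed = dataset$seed, file = files)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' @rdname write_fhr_dataset
#' @export
read_fhr_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path))
    rlang::abort("no manifest.csv in dataset directory",
                 class = "fhrscreen_input_error")
  manifest <- utils::read.csv(manifest_path)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    tr <- read_fhr_trace(file.path(dir, manifest$file[i]),
                         id = manifest$id[i])
    tibble::tibble(id = manifest$id[i], label = manifest$label[i],
                   seed = manifest$seed[i], trace = list(tr),
                   events = list(NULL))
  })
  dplyr::bind_rows(rows)
}
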