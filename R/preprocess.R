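#' Correct spike artifacts
#'
#' Single-sample spikes — transducer artifacts where one sample differs from
#' both of its neighbours by more than `jump_bpm` — are replaced by the mean
#' of the two neighbours. Dropout samples (0 bpm) are left untouched; they are
#' the business of [remove_missing_beats()].
#'
#' @param trace an [fhr_trace()] or numeric vector (bpm).
#' @param jump_bpm spike threshold in bpm (default 25).
#' @return list with `trace` (corrected, same type as input) and
#'   `n_corrected`.
#' @export
despike <- function(trace, jump_bpm = 25) {
  stopifnot(jump_bpm > 0)
  x <- as_fhr_values(trace)
  n <- length(x)
  n_corrected <- 0L
  if (n >= 3) {
    i <- 2:(n - 1)
    prev <- x[i - 1]
    nxt <- x[i + 1]
    spike <- abs(x[i] - prev) > jump_bpm & abs(x[i] - nxt) > jump_bpm &
      x[i] != 0 & prev != 0 & nxt != 0
    idx <- i[spike]
    if (length(idx)) {
      x[idx] <- (x[idx - 1] + x[idx + 1]) / 2
      n_corrected <- length(idx)
    }
  }
  out <- if (inherits(trace, "fhr_trace"))
    fhr_trace(x, fs = fhr_fs(trace), id = fhr_id(trace), time_s = trace$time_s)
  else x
  list(trace = out, n_corrected = n_corrected)
}

#' Remove missing beats
#'
#' Recursively excises maximal runs of missing samples — values encoded as 0
#' or falling outside the physiological band `bpm_range` — and concatenates
#' the remaining segments. A trace losing more than `max_missing` of its
#' samples is flagged unusable and excluded from analysis; dropout above that
#' level is beyond the regime the method is designed for.
#'
#' Runs no longer than `interp_max_s` seconds can instead be bridged by
#' linear interpolation (`interp_max_s = 0`, the default, disables this and
#' always excises).
#'
#' @param trace an [fhr_trace()] or numeric vector (bpm).
#' @param bpm_range two-element numeric: valid FHR band, default c(50, 220).
#' @param max_missing usability cutoff on the missing fraction (default 0.4).
#' @param interp_max_s gaps of at most this many seconds are filled by linear
#'   interpolation instead of excision.
#' @return list with `trace` (cleaned [fhr_trace()]) and `report`, a tibble
#'   with `n_missing_removed`, `fraction_missing`, `n_interpolated`, `usable`.
#' @export
remove_missing_beats <- function(trace, bpm_range = c(50, 220),
                                 max_missing = 0.4, interp_max_s = 0) {
  x <- as_fhr_values(trace)
  fs <- fhr_fs(trace)
  n <- length(x)
  bad <- !is.finite(x) | x == 0 | x < bpm_range[1] | x > bpm_range[2]
  n_interp <- 0L
  if (interp_max_s > 0 && any(bad) && !all(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      if (r$lengths[j] / fs <= interp_max_s &&
          starts[j] > 1L && ends[j] < n) {
        idx <- starts[j]:ends[j]
        x[idx] <- x[starts[j] - 1L] +
          (x[ends[j] + 1L] - x[starts[j] - 1L]) *
          (idx - starts[j] + 1L) / (r$lengths[j] + 1L)
        bad[idx] <- FALSE
        n_interp <- n_interp + r$lengths[j]
      }
    }
  }
  kept <- excise_runs(x, bad)
  n_removed <- n - length(kept)
  frac <- if (n) (n_removed + n_interp) / n else 0
  report <- tibble::tibble(
    n_missing_removed = n_removed,
    fraction_missing = frac,
    n_interpolated = n_interp,
    usable = frac <= max_missing)
  out <- fhr_trace(kept, fs = fs, id = fhr_id(trace))
  list(trace = out, report = report)
}

# recursive excision: drop the first maximal bad run, recurse on the rest
excise_runs <- function(x, bad) {
  first <- which(bad)[1]
  if (is.na(first)) return(x)
  last <- first
  while (last < length(x) && bad[last + 1L]) last <- last + 1L
  keep_head <- if (first > 1L) seq_len(first - 1L) else integer(0)
  tail_idx <- if (last < length(x)) (last + 1L):length(x) else integer(0)
  c(x[keep_head], excise_runs(x[tail_idx], bad[tail_idx]))
}

#' Clean an FHR trace
#'
#' The standard artifact chain: spike correction first, then missing-beat
#' removal.
#'
#' @inheritParams remove_missing_beats
#' @param jump_bpm spike threshold in bpm.
#' @return list with `trace` and `report` (the missing-beat report plus a
#'   `n_spikes_corrected` column).
#' @export
clean_fhr <- function(trace, jump_bpm = 25, bpm_range = c(50, 220),
                      max_missing = 0.4, interp_max_s = 0) {
  d <- despike(trace, jump_bpm = jump_bpm)
  m <- remove_missing_beats(d$trace, bpm_range = bpm_range,
                            max_missing = max_missing,
                            interp_max_s = interp_max_s)
  m$report$n_spikes_corrected <- d$n_corrected
  m
}

#' Estimate the noise order of a decomposition
#'
#' Low-order IMFs carrying high-frequency noise have zero mean. For
#' M = 1, 2, ... the partial sum of the first M IMFs is tested against H0:
#' its mean is zero (one-sample two-sided t-test over samples). The t-test
#' order `p_t` is the largest M before the first rejection; to avoid
#' over-smoothing, the final noise order is capped at three:
#' `p_f = min(p_t, 3)`. The first `p_f` components are then treated as noise.
#'
#' @param dec an [emd()] decomposition with at least one IMF.
#' @param alpha significance level in (0, 0.5); default 0.05.
#' @return a tibble with `p_t`, `p_f`, `alpha`, and `p_values` (list-column
#'   of the per-M t-test p-values).
#' @export
estimate_noise_order <- function(dec, alpha = 0.05) {
  stopifnot(inherits(dec, "emd_decomposition"))
  if (n_imfs(dec) < 1)
    rlang::abort("decomposition has no IMFs", class = "fhrscreen_input_error")
  stopifnot(alpha > 0, alpha < 0.5)
  p_values <- numeric(0)
  p_t <- 0L
  partial <- rep(0, nrow(dec$imfs))
  for (m in seq_len(n_imfs(dec))) {
    partial <- partial + dec$imfs[, m]
    p <- partial_sum_pvalue(partial)
    p_values <- c(p_values, p)
    if (p < alpha) break
    p_t <- m
  }
  tibble::tibble(p_t = p_t, p_f = min(p_t, 3L), alpha = alpha,
                 p_values = list(p_values))
}

partial_sum_pvalue <- function(x) {
  # a numerically constant partial sum cannot reject H0: mean = 0
  if (stats::sd(x) < 1e-12 * (abs(mean(x)) + 1e-12)) {
    if (abs(mean(x)) < 1e-12) return(1)
    return(0)
  }
  stats::t.test(x, mu = 0)$p.value
}

#' Strip the noise components from a decomposition
#'
#' Partial reconstruction over the retained components: the first `p_f`
#' (fastest) components are discarded and the denoised signal is the sum of
#' components `p_f + 1` through `n_imfs_total` (residue included).
#'
#' @param dec an [emd()] decomposition.
#' @param order the noise order, as returned by [estimate_noise_order()], or
#'   a single non-negative integer `p_f`.
#' @return list with `denoised` (numeric vector) and `retained` (matrix of
#'   retained components, fast to slow, residue last).
#' @export
denoise <- function(dec, order) {
  stopifnot(inherits(dec, "emd_decomposition"))
  p_f <- if (is.data.frame(order)) order$p_f[[1]] else as.integer(order)
  stopifnot(p_f >= 0)
  comps <- emd_components(dec)
  if (p_f >= ncol(comps))
    rlang::abort("noise order leaves no components to retain",
                 class = "fhrscreen_input_error")
  retained <- comps[, (p_f + 1L):ncol(comps), drop = FALSE]
  list(denoised = rowSums(retained), retained = retained, p_f = p_f)
}
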