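#' Construct an FHR trace
#'
#' An FHR trace is a tibble with columns `time_s` (seconds) and `fhr_bpm`
#' (beats per minute), a sampling rate carried as an attribute, and an id.
#' Antepartum cardiotocography monitors emit the heart-rate channel at 4 Hz,
#' which is the default.
#'
#' @param fhr_bpm numeric vector of heart-rate samples (bpm). Dropouts are
#'   conventionally encoded as 0.
#' @param fs sampling rate in Hz (default 4).
#' @param id character label for the trace.
#' @param time_s optional explicit time stamps; defaults to a uniform grid
#'   starting at 0.
#' @return a tibble of class `fhr_trace` with columns `time_s`, `fhr_bpm`.
#' @examples
#' tr <- fhr_trace(120 + 5 * sin(2 * pi * 0.1 * (0:99) / 4))
#' fhr_fs(tr)
#' @export
fhr_trace <- function(fhr_bpm, fs = 4, id = "trace", time_s = NULL) {
  stopifnot(is.numeric(fhr_bpm), length(fs) == 1, fs > 0)
  if (is.null(time_s)) time_s <- (seq_along(fhr_bpm) - 1) / fs
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        fhr_bpm = as.numeric(fhr_bpm))
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "id") <- as.character(id)
  class(out) <- c("fhr_trace", class(out))
  out
}

#' @rdname fhr_trace
#' @param x an `fhr_trace`.
#' @export
fhr_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) 4 else fs
}

#' @rdname fhr_trace
#' @export
fhr_id <- function(x) {
  id <- attr(x, "id")
  if (is.null(id)) "trace" else id
}

as_fhr_values <- function(x) {
  if (inherits(x, "fhr_trace") || (is.data.frame(x) && "fhr_bpm" %in% names(x)))
    return(x$fhr_bpm)
  if (is.numeric(x)) return(as.numeric(x))
  rlang::abort("expected an fhr_trace, a data frame with `fhr_bpm`, or a numeric vector",
               class = "fhrscreen_input_error")
}

#' Read / write an FHR trace as two-column delimited text
#'
#' The on-disk format is `time_s,fhr_bpm` with an optional header and optional
#' `#`-prefixed comment lines. When time stamps are absent (single column) a
#' 4 Hz grid is assumed.
#'
#' @param path file path.
#' @param fs sampling rate assumed when the file has no time column.
#' @param id trace id; defaults to the file name.
#' @return `read_fhr_trace()` returns an [fhr_trace()].
#' @export
read_fhr_trace <- function(path, fs = 4, id = NULL) {
  if (!file.exists(path))
    rlang::abort(paste0("trace file not found: ", path),
                 class = "fhrscreen_input_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    rlang::abort("empty trace file", class = "fhrscreen_input_error")
  has_header <- grepl("[A-Za-z]", lines[[1]])
  if (has_header) lines <- lines[-1]
  fields <- strsplit(lines, "[,\t ]+")
  ncol <- length(fields[[1]])
  vals <- suppressWarnings(vapply(fields, function(f) as.numeric(f[ncol]), 0))
  if (anyNA(vals))
    rlang::abort("non-numeric values in trace file",
                 class = "fhrscreen_input_error")
  if (ncol >= 2) {
    ts <- suppressWarnings(vapply(fields, function(f) as.numeric(f[1]), 0))
    dt <- diff(ts)
    if (length(dt) && all(is.finite(dt)) && all(dt > 0)) fs <- 1 / stats::median(dt)
    fhr_trace(vals, fs = fs, id = id %||% basename(path), time_s = ts)
  } else {
    fhr_trace(vals, fs = fs, id = id %||% basename(path))
  }
}

#' @rdname read_fhr_trace
#' @param trace an [fhr_trace()].
#' @param config optional list embedded as `#`-comment header lines so the
#'   producing run's parameters travel with the artifact.
#' @export
write_fhr_trace <- function(trace, path, config = NULL) {
  vals <- as_fhr_values(trace)
  ts <- if (is.data.frame(trace) && "time_s" %in% names(trace)) trace$time_s
        else (seq_along(vals) - 1) / fhr_fs(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  writeLines("time_s,fhr_bpm", con)
  writeLines(paste(sprintf("%.12g", ts), sprintf("%.12g", vals), sep = ","),
             con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
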