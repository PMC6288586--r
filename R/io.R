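#' Read a respiratory signal from CSV
#'
#' Two dialects are accepted:
#' * a single `value` column — `dt` must then be supplied;
#' * `time,value` columns — `dt` is inferred as the median first
#'   difference of `time` unless overridden. The time column must be
#'   strictly increasing; a warning is issued if any first difference
#'   deviates from the median by more than 1% (the grid is still treated
#'   as exactly uniform).
#'
#' Non-numeric, NA/NaN/Inf values are rejected.
#'
#' @param path CSV file path.
#' @param dt sampling interval override in seconds.
#' @return A [resp_signal()].
#' @export
read_signal <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!"value" %in% names(df)) {
    if (ncol(df) == 1L) names(df) <- "value"
    else stop("CSV must have a `value` column (optionally with `time`)",
              call. = FALSE)
  }
  if (!is.numeric(df$value)) {
    stop("`value` column is not numeric", call. = FALSE)
  }
  origin <- 0
  if ("time" %in% names(df)) {
    tcol <- df$time
    if (!is.numeric(tcol) || anyNA(tcol) || any(!is.finite(tcol))) {
      stop("`time` column is not finite numeric", call. = FALSE)
    }
    d <- diff(tcol)
    if (any(d <= 0)) stop("`time` column must be strictly increasing",
                          call. = FALSE)
    med <- stats::median(d)
    if (any(abs(d - med) > 0.01 * med)) {
      warning("time grid deviates from uniform by more than 1%; ",
              "treating dt as the median step ", signif(med, 6),
              call. = FALSE)
    }
    dt <- dt %||% med
    origin <- tcol[1]
  } else if (is.null(dt)) {
    stop("`dt` is required for a single-column CSV", call. = FALSE)
  }
  resp_signal(df$value, dt = dt, origin_time = origin)
}

#' Write a respiratory signal to CSV
#'
#' Writes the `time,value` dialect read back by [read_signal()].
#'
#' @param signal a [resp_signal()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "resp_signal"))
  utils::write.csv(
    data.frame(time = signal_times(signal), value = signal$values),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a gate trace to CSV
#'
#' One row per sample with columns `index` (1-based), `time_s`,
#' `value_mm`, `gate_state`, `in_scored_set`. Integer states round-trip
#' losslessly.
#'
#' @param trace a [gate_trace()].
#' @param signal the [resp_signal()] it was simulated from.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, signal, path) {
  stopifnot(inherits(trace, "gate_trace"), inherits(signal, "resp_signal"))
  if (length(trace$states) != length(signal$values)) {
    stop("trace and signal lengths differ", call. = FALSE)
  }
  df <- data.frame(
    index = seq_along(signal$values),
    time_s = signal_times(signal),
    value_mm = signal$values,
    gate_state = trace$states,
    in_scored_set = as.integer(seq_along(signal$values) %in% trace$scored)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert a raw monitoring-device export to the package CSV dialect
#'
#' Bridge for externally measured respiratory traces (e.g. the publicly
#' archived Abches recordings): reads a whitespace- or comma-separated
#' two-column (time, value) or one-column (value) text file, takes the
#' value column, and writes a standard `time,value` CSV on an exactly
#' uniform grid at `dt` — device timestamps are close to but not exactly
#' uniform, and the analysis assumes a fixed grid.
#'
#' This helper is a format converter only; full-scale runs on real
#' recordings are driven by the user through [run_experiment()].
#'
#' @param path raw export path.
#' @param out output CSV path.
#' @param dt grid interval in seconds (default 0.03).
#' @param header does the raw file have a header line?
#' @return Invisibly, `out`.
#' @export
import_device_export <- function(path, out, dt = 0.03, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = header, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) == 1L) {
    # maybe comma-separated after all
    if (is.character(raw[[1]]) && any(grepl(",", raw[[1]]))) {
      raw <- utils::read.table(path, header = header, sep = ",",
                               comment.char = "#",
                               stringsAsFactors = FALSE)
    }
  }
  values <- raw[[ncol(raw)]] # value column is the last one
  values <- suppressWarnings(as.numeric(values))
  if (anyNA(values)) stop("non-numeric values in ", path, call. = FALSE)
  sig <- resp_signal(values, dt = dt)
  write_signal(sig, out)
  invisible(out)
}
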