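#' Respiratory signal
#'
#' A uniformly sampled 1-D respiratory amplitude series. Amplitudes are in
#' millimetres, the sampling interval `dt` in seconds. Sample `i` (1-based)
#' is taken at time `origin_time + (i - 1) * dt`.
#'
#' @param values numeric vector of amplitudes (mm); must be finite.
#' @param dt sampling interval in seconds; must be a single positive number.
#' @param origin_time time of the first sample in seconds.
#'
#' @return An object of class `resp_signal`: a list with elements `values`,
#'   `dt` and `origin_time`.
#' @examples
#' sig <- resp_signal(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.03)
#' length(sig)
#' @export
resp_signal <- function(values, dt, origin_time = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("`values` must contain at least one sample", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite: NA/NaN/Inf are rejected at ingestion",
         call. = FALSE)
  }
  structure(list(values = values, dt = dt, origin_time = as.numeric(origin_time)),
            class = "resp_signal")
}

#' @export
length.resp_signal <- function(x) length(x$values)

#' Sample times of a respiratory signal
#'
#' @param signal a [resp_signal()].
#' @return Numeric vector of times (s), one per sample.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "resp_signal"))
  signal$origin_time + (seq_along(signal$values) - 1) * signal$dt
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf(
    "<resp_signal> %d samples at dt = %g s (%.2f s), amplitude [%.3f, %.3f] mm\n",
    length(x$values), x$dt, length(x$values) * x$dt,
    min(x$values), max(x$values)))
  invisible(x)
}

# ceiling(x / dt) with a guard against floating-point round-up of exact
# multiples (e.g. 0.3 / 0.03 can exceed 10 in doubles)
seconds_to_points <- function(x, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("seconds must be finite and non-negative", call. = FALSE)
  }
  as.integer(ceiling(x / dt - 1e-9))
}

#' Convert a gating latency in seconds to sampling points
#'
#' Latencies are converted by `ceiling(delay / dt)`: a delay that falls
#' between two grid points must be rounded up, since the command cannot
#' execute before the delay has fully elapsed.
#'
#' @param delay gate on/off delay in seconds (non-negative).
#' @param dt sampling interval in seconds.
#' @return Integer number of sampling points.
#' @examples
#' latency_to_points(0.336, 0.03) # 12
#' latency_to_points(0.088, 0.03) # 3
#' @export
latency_to_points <- function(delay, dt) seconds_to_points(delay, dt)

#' Convert a duration in seconds to a number of samples
#'
#' Uses the same ceiling convention as [latency_to_points()]; a 20 s
#' recording at dt = 0.03 s spans 667 points.
#'
#' @param duration duration in seconds (non-negative).
#' @param dt sampling interval in seconds.
#' @return Integer number of samples.
#' @export
duration_to_points <- function(duration, dt) seconds_to_points(duration, dt)

#' Amplitude gating threshold from an initial signal segment
#'
#' The gating threshold beta is fixed to the median of the first `N`
#' samples of the signal. For even `N` the median is the mean of the two
#' central order statistics.
#'
#' @param signal a [resp_signal()].
#' @param N number of leading samples over which the median is taken.
#' @return Threshold beta in mm.
#' @export
gating_threshold <- function(signal, N) {
  stopifnot(inherits(signal, "resp_signal"))
  N <- as.integer(N)
  if (N < 1L || N > length(signal$values)) {
    stop("`N` must be between 1 and the signal length", call. = FALSE)
  }
  stats::median(signal$values[seq_len(N)])
}

#' Gating-system latency profile
#'
#' Published gate on/off latencies of commercial gating systems, used as
#' simulation presets. Delays are in seconds.
#'
#' @param name one of `"abches"`, `"alignrt"`, `"calypso"`, `"catalyst"`,
#'   or `"custom"` (then `gate_on_s`/`gate_off_s` must be supplied).
#' @param dt sampling interval used to express the delays in points.
#' @param gate_on_s,gate_off_s delays in seconds for `name = "custom"`.
#' @return A list with elements `name`, `gate_on_s`, `gate_off_s`, and the
#'   corresponding point counts `m1`, `m0` at the given `dt`.
#' @examples
#' latency_profile("abches", dt = 0.03) # m1 = 12, m0 = 3
#' @export
latency_profile <- function(name, dt = 0.03, gate_on_s = NULL, gate_off_s = NULL) {
  name <- match.arg(tolower(name),
                    c("abches", "alignrt", "calypso", "catalyst", "custom"))
  tab <- latency_profiles()
  if (name == "custom") {
    if (is.null(gate_on_s) || is.null(gate_off_s)) {
      stop("custom profile needs `gate_on_s` and `gate_off_s`", call. = FALSE)
    }
  } else {
    row <- tab[tab$system == name, ]
    gate_on_s <- row$gate_on_s
    gate_off_s <- row$gate_off_s
  }
  if (gate_on_s < 0 || gate_off_s < 0) {
    stop("latencies must be non-negative", call. = FALSE)
  }
  list(name = name, gate_on_s = gate_on_s, gate_off_s = gate_off_s,
       m1 = latency_to_points(gate_on_s, dt),
       m0 = latency_to_points(gate_off_s, dt))
}

#' Table of published gating-system latencies
#'
#' @return A data.frame with columns `system`, `gate_on_s`, `gate_off_s`.
#' @export
latency_profiles <- function() {
  data.frame(
    system     = c("abches", "alignrt", "calypso", "catalyst"),
    gate_on_s  = c(0.336, 0.356, 0.209, 0.851),
    gate_off_s = c(0.088, 0.529, 0.060, 0.215),
    stringsAsFactors = FALSE
  )
}
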