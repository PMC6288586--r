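#' Euclidean distance between two equal-length tuples
#'
#' @param a,b numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  if (length(a) == 0L) stop("tuples must be non-empty", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Build a learning set of (history, future) pairs from a signal window
#'
#' The window of `N` raw samples is first smoothed (unless `smoothing` is
#' `NULL`), then every overlapping pair of an `n`-point history and the
#' `m`-point future that follows it is extracted at stride 1. A window of
#' `N` points yields `N - n - m + 1` ordered pairs; their index order is
#' the tie-breaking order used by [nn_predict()].
#'
#' @param window numeric vector of `N` raw samples.
#' @param n history length in points.
#' @param m future (prediction horizon) length in points.
#' @param smoothing a [smoothing_config()] applied to the window before
#'   slicing, or `NULL` for no smoothing.
#' @param dt sampling interval, needed when the smoothing cutoff is in Hz.
#' @return An object of class `learning_set`: a list with `histories`
#'   (K x n matrix), `futures` (K x m matrix), `n` and `m`.
#' @examples
#' ls <- learning_set(0:4, n = 2, m = 1)
#' ls$histories # rows (0,1), (1,2), (2,3)
#' @export
learning_set <- function(window, n, m, smoothing = NULL, dt = NULL) {
  window <- as.numeric(window)
  N <- length(window)
  n <- as.integer(n); m <- as.integer(m)
  if (n < 1L || m < 1L) stop("`n` and `m` must be positive", call. = FALSE)
  if (n + m > N) {
    stop("`n + m` must not exceed the window length", call. = FALSE)
  }
  sw <- if (is.null(smoothing)) {
    window
  } else {
    smooth_window(window, resolve_alpha(smoothing, N, dt %||% 1))
  }
  K <- N - n - m + 1L
  hidx <- outer(seq_len(K), 0:(n - 1L), "+")
  fidx <- outer(seq_len(K) + n, 0:(m - 1L), "+")
  histories <- sw[hidx]; dim(histories) <- dim(hidx)
  futures <- sw[fidx]; dim(futures) <- dim(fidx)
  structure(list(histories = histories, futures = futures, n = n, m = m),
            class = "learning_set")
}

#' @export
print.learning_set <- function(x, ...) {
  cat(sprintf("<learning_set> %d entries: history n = %d, future m = %d\n",
              nrow(x$histories), x$n, x$m))
  invisible(x)
}

#' Nearest-neighbour multistep-ahead prediction
#'
#' Returns the future tuple paired with the learning-set history nearest
#' (Euclidean) to `test_history`. Among histories at exactly the minimal
#' distance, the one with the largest index wins — the most recent match
#' is preferred.
#'
#' @param ls a [learning_set()].
#' @param test_history numeric vector of length `ls$n`.
#' @return Numeric vector of length `ls$m`: the predicted future tuple.
#'   Always one of the learning set's stored futures (no interpolation).
#' @export
nn_predict <- function(ls, test_history) {
  if (!inherits(ls, "learning_set")) {
    stop("`ls` must be a learning_set", call. = FALSE)
  }
  K <- nrow(ls$histories)
  if (K == 0L) stop("learning set is empty", call. = FALSE)
  if (length(test_history) != ls$n) {
    stop("`test_history` must have length n = ", ls$n, call. = FALSE)
  }
  d2 <- rowSums((ls$histories - rep(as.numeric(test_history), each = K))^2)
  p <- max(which(d2 == min(d2)))
  ls$futures[p, ]
}

#' Predictor configuration for rolling serial prediction
#'
#' @param N learning-window length in points.
#' @param n history length in points.
#' @param m prediction horizon in points.
#' @param smoothing a [smoothing_config()] applied to each learning window,
#'   or `NULL` to disable smoothing.
#' @param smooth_test_history should the query history be smoothed too?
#'   Default `FALSE`: learning entries are smoothed but the query is the
#'   raw recent history, matching the gating rule's definition.
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(N, n, m, smoothing = NULL,
                             smooth_test_history = FALSE) {
  N <- as.integer(N); n <- as.integer(n); m <- as.integer(m)
  if (N < 1L || n < 1L || m < 1L) {
    stop("`N`, `n`, `m` must be positive", call. = FALSE)
  }
  if (n + m > N) stop("`n + m` must not exceed `N`", call. = FALSE)
  if (!is.null(smoothing) && !inherits(smoothing, "smoothing_config")) {
    stop("`smoothing` must be a smoothing_config or NULL", call. = FALSE)
  }
  structure(list(N = N, n = n, m = m, smoothing = smoothing,
                 smooth_test_history = isTRUE(smooth_test_history)),
            class = "predictor_config")
}

#' Rolling serial multistep-ahead prediction over a signal
#'
#' For each prediction origin `t` (1-based index of the first predicted
#' sample), the `N` raw samples ending at `t - n - 1` form the learning
#' window; a fresh learning set is built from it (with smoothing), and the
#' raw history `(x[t-n], ..., x[t-1])` is the query. The valid range of
#' `t` is `N + n + 1, ..., M - m + 1`, giving `M - N - n - m + 1` trials
#' over a signal of length `M`.
#'
#' @param signal a [resp_signal()].
#' @param config a [predictor_config()].
#' @param t_range integer vector of prediction origins; default the full
#'   valid range.
#' @return An object of class `rolling_prediction`: a list with `t`,
#'   `predicted` (matrix, one row per origin), `predicted_last` and
#'   `actual_last` (the m-th predicted coordinate and the observation it
#'   targets), plus the configuration.
#' @export
rolling_predict <- function(signal, config, t_range = NULL) {
  stopifnot(inherits(signal, "resp_signal"),
            inherits(config, "predictor_config"))
  x <- signal$values
  M <- length(x)
  N <- config$N; n <- config$n; m <- config$m
  if (M < N + n + m) {
    stop("signal too short: need at least N + n + m samples", call. = FALSE)
  }
  t_lo <- N + n + 1L; t_hi <- M - m + 1L
  t_range <- if (is.null(t_range)) t_lo:t_hi else as.integer(t_range)
  if (any(t_range < t_lo | t_range > t_hi)) {
    stop(sprintf("`t_range` must lie within [%d, %d]", t_lo, t_hi),
         call. = FALSE)
  }
  alpha <- resolve_alpha(config$smoothing, N, signal$dt)
  K <- N - n - m + 1L
  hidx <- outer(seq_len(K), 0:(n - 1L), "+")
  predicted <- matrix(NA_real_, length(t_range), m)
  for (j in seq_along(t_range)) {
    t <- t_range[j]
    win <- x[(t - n - N):(t - n - 1L)]
    sw <- if (is.null(alpha)) win else smooth_window(win, alpha)
    th <- x[(t - n):(t - 1L)]
    if (config$smooth_test_history && !is.null(alpha)) {
      th <- smooth_window(th, resolve_alpha(config$smoothing, n, signal$dt))
    }
    H <- sw[hidx]; dim(H) <- dim(hidx)
    d2 <- rowSums((H - rep(th, each = K))^2)
    p <- max(which(d2 == min(d2)))
    predicted[j, ] <- sw[(p + n):(p + n + m - 1L)]
  }
  structure(list(t = t_range, predicted = predicted,
                 predicted_last = predicted[, m],
                 actual_last = x[t_range + m - 1L],
                 config = config),
            class = "rolling_prediction")
}

#' @export
print.rolling_prediction <- function(x, ...) {
  cat(sprintf(
    "<rolling_prediction> %d trials, horizon m = %d; RMSE (last coord) = %.4g mm\n",
    length(x$t), x$config$m, prediction_rmse(x)))
  invisible(x)
}

#' Root-mean-square prediction error
#'
#' For a [rolling_prediction()], scores only the m-th predicted coordinate
#' against the observation at the same index, averaged over all trials —
#' the standard serial-prediction error for an m-step-ahead forecaster.
#' Can also be called on two bare numeric vectors.
#'
#' @param predicted a `rolling_prediction` or numeric vector.
#' @param actual numeric vector (ignored for a `rolling_prediction`).
#' @return RMSE in mm.
#' @export
prediction_rmse <- function(predicted, actual = NULL) {
  if (inherits(predicted, "rolling_prediction")) {
    actual <- predicted$actual_last
    predicted <- predicted$predicted_last
  }
  if (length(predicted) != length(actual)) {
    stop("`predicted` and `actual` must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0L) stop("inputs must be non-empty", call. = FALSE)
  sqrt(mean((predicted - actual)^2))
}

#' Mean per-step RMSE over the full prediction horizon
#'
#' Extra diagnostic beyond [prediction_rmse()]: RMSE of every predicted
#' coordinate (1 to m steps ahead) against the corresponding observations.
#'
#' @param rp a `rolling_prediction`.
#' @param signal the [resp_signal()] it was computed from.
#' @return Numeric vector of length m: RMSE per look-ahead step.
#' @export
horizon_rmse <- function(rp, signal) {
  stopifnot(inherits(rp, "rolling_prediction"),
            inherits(signal, "resp_signal"))
  m <- rp$config$m
  vapply(seq_len(m), function(k) {
    prediction_rmse(rp$predicted[, k], signal$values[rp$t + k - 1L])
  }, numeric(1))
}
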