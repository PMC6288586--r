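#' Hamming window weights
#'
#' Weights `w_k = 0.54 - 0.46 * cos(2*pi*k/(N-1))` for `k = 0, ..., N-1`.
#' All weights lie in `[0.08, 1]` and the sequence is symmetric, so the
#' window is invertible by elementwise division.
#'
#' @param N window length; must be at least 2.
#' @return Numeric vector of `N` positive weights.
#' @examples
#' hamming_weights(4) # 0.08 0.77 0.77 0.08
#' @export
hamming_weights <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) {
    stop("`N` must be an integer >= 2", call. = FALSE)
  }
  k <- 0:(N - 1)
  0.54 - 0.46 * cos(2 * pi * k / (N - 1))
}

#' Low-pass frequency mask for a length-N spectrum
#'
#' Zeroes Fourier coefficient `k` (0-based) iff `|k - N/2| < N/2 - alpha`
#' (strict inequality); all other coefficients pass unchanged. The kept
#' index set is symmetric under `k -> N - k`, so masking the spectrum of a
#' real signal leaves it conjugate-symmetric. `alpha >= N/2` keeps every
#' coefficient.
#'
#' @param coefficients complex vector of `N` Fourier coefficients.
#' @param alpha non-negative real cutoff in frequency bins (need not be an
#'   integer); see [alpha_from_cutoff()].
#' @return The masked coefficient vector.
#' @export
frequency_mask <- function(coefficients, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  }
  N <- length(coefficients)
  k <- 0:(N - 1)
  coefficients[abs(k - N / 2) < N / 2 - alpha] <- 0
  coefficients
}

#' Convert a cutoff frequency in Hz to the mask parameter alpha
#'
#' `alpha = N * dt * f`. The result is kept real (not rounded); the strict
#' mask inequality in [frequency_mask()] consumes real alpha directly.
#'
#' @param f cutoff frequency in Hz; must satisfy `0 <= f <= 1/(2*dt)`
#'   (Nyquist).
#' @param N window length in points.
#' @param dt sampling interval in seconds.
#' @return alpha, in frequency bins.
#' @examples
#' alpha_from_cutoff(1, 667, 0.03) # 20.01
#' @export
alpha_from_cutoff <- function(f, N, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) ||
      f < 0 || f > 1 / (2 * dt)) {
    stop("`f` must lie in [0, 1/(2*dt)] Hz", call. = FALSE)
  }
  N * dt * f
}

#' Smoothing configuration
#'
#' Specifies the low-pass smoothing applied to learning windows: either a
#' mask parameter `alpha` (in bins, fixed regardless of window length) or a
#' cutoff frequency `cutoff_hz` (converted to alpha per window via
#' [alpha_from_cutoff()]). Exactly one of the two must be given.
#'
#' @param cutoff_hz cutoff frequency in Hz.
#' @param alpha mask parameter in bins.
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(cutoff_hz = NULL, alpha = NULL) {
  if (is.null(cutoff_hz) == is.null(alpha)) {
    stop("give exactly one of `cutoff_hz` or `alpha`", call. = FALSE)
  }
  if (!is.null(alpha) &&
      (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)) {
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(cutoff_hz) &&
      (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz < 0)) {
    stop("`cutoff_hz` must be a single non-negative number", call. = FALSE)
  }
  structure(list(cutoff_hz = cutoff_hz, alpha = alpha),
            class = "smoothing_config")
}

# resolve a smoothing spec to a numeric alpha for a window of length N
# sampled at dt; NULL means smoothing disabled and returns NULL
resolve_alpha <- function(smoothing, N, dt) {
  if (is.null(smoothing)) return(NULL)
  if (!inherits(smoothing, "smoothing_config")) {
    stop("`smoothing` must be a smoothing_config or NULL", call. = FALSE)
  }
  if (!is.null(smoothing$alpha)) return(smoothing$alpha)
  alpha_from_cutoff(smoothing$cutoff_hz, N, dt)
}

# core smoothing chain on a bare numeric window:
# Hamming multiply -> forward FFT -> low-pass mask -> inverse FFT ->
# real part -> Hamming divide.  stats::fft matches the pinned transform
# convention (unnormalized forward, 1/N on the inverse).
smooth_window <- function(x, alpha) {
  N <- length(x)
  if (N < 2L) stop("window must have at least 2 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("window must be finite", call. = FALSE)
  w <- hamming_weights(N)
  if (any(w < 1e-12)) stop("degenerate Hamming weights", call. = FALSE)
  s <- stats::fft(w * x)
  s <- frequency_mask(s, alpha)
  u <- stats::fft(s, inverse = TRUE) / N
  Re(u) / w
}

#' Low-pass smooth a signal by windowed finite Fourier transform
#'
#' Applies the smoothing operator: the window is multiplied by the Hamming
#' weights, transformed by the finite Fourier transform, high-frequency
#' coefficients are zeroed by [frequency_mask()], the inverse transform is
#' applied, the real part taken, and the Hamming weights divided out.
#'
#' With `alpha >= N/2` the mask keeps everything and the operator is the
#' identity (up to rounding). The operator is linear and idempotent.
#'
#' @param x a [resp_signal()] or a bare numeric window.
#' @param smoothing a [smoothing_config()]; alternatively pass `alpha` or
#'   `cutoff_hz` directly.
#' @param cutoff_hz,alpha shorthand for `smoothing = smoothing_config(...)`.
#' @param dt sampling interval; required when `x` is a bare vector and the
#'   cutoff is given in Hz.
#' @return Smoothed object of the same kind as `x`.
#' @examples
#' sig <- resp_signal(cos(2 * pi * 0.25 * (0:666) * 0.03)^4, dt = 0.03)
#' sm <- fourier_smooth(sig, cutoff_hz = 1)
#' @export
fourier_smooth <- function(x, smoothing = NULL, cutoff_hz = NULL,
                           alpha = NULL, dt = NULL) {
  if (is.null(smoothing)) {
    smoothing <- smoothing_config(cutoff_hz = cutoff_hz, alpha = alpha)
  }
  if (inherits(x, "resp_signal")) {
    a <- resolve_alpha(smoothing, length(x$values), x$dt)
    return(resp_signal(smooth_window(x$values, a), dt = x$dt,
                       origin_time = x$origin_time))
  }
  x <- as.numeric(x)
  if (is.null(smoothing$alpha) && is.null(dt)) {
    stop("`dt` is required to resolve a cutoff in Hz for a bare vector",
         call. = FALSE)
  }
  a <- resolve_alpha(smoothing, length(x), dt %||% 1)
  smooth_window(x, a)
}

#' One-sided power spectrum of a Hamming-windowed window
#'
#' Returns `|s_k|` for `k = 0, ..., floor((N-1)/2)`, where `s` is the
#' finite Fourier transform of the Hamming-windowed input — the display
#' used to inspect which components a cutoff removes.
#'
#' @param x a [resp_signal()] or numeric vector.
#' @return A data.frame with columns `freq_hz` (NA if `dt` unknown) and
#'   `power`.
#' @export
power_spectrum <- function(x) {
  dt <- NA_real_
  if (inherits(x, "resp_signal")) {
    dt <- x$dt
    x <- x$values
  }
  N <- length(x)
  s <- stats::fft(hamming_weights(N) * x)
  k <- 0:((N - 1) %/% 2)
  data.frame(freq_hz = if (is.na(dt)) NA_real_ else k / (N * dt),
             power = Mod(s[k + 1]))
}
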