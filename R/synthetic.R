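#' Parameters of the synthetic respiratory-signal generator
#'
#' The generator emulates quiet breathing as
#' `b0 + A * cos(pi * t / T + phase)^(2p)` — an even cosine power, the
#' standard waveform with a long exhalation plateau near the baseline and
#' brief inhalation peaks — optionally perturbed by cycle-wise amplitude
#' and period jitter, additive white noise, baseline drift, and a
#' high-frequency noise burst.
#'
#' @param baseline resting amplitude b0 (mm).
#' @param amplitude peak excursion A above baseline (mm), >= 0.
#' @param period breathing period T (s), > 0.
#' @param shape_exponent positive integer p; the waveform uses the power
#'   `2p`. Larger p gives a flatter exhalation plateau.
#' @param phase phase offset (radians).
#' @param amp_jitter relative s.d. of per-cycle amplitude scaling.
#' @param period_jitter relative s.d. of per-cycle period scaling.
#' @param noise_sd additive white-noise s.d. (mm).
#' @param drift_rate baseline drift rate (mm/s) for `drift_mode "linear"`;
#'   for `"random_walk"` it scales the diffusion so the drift s.d. after
#'   `t` seconds is `drift_rate * sqrt(t)`.
#' @param drift_mode `"linear"` (default) or `"random_walk"`.
#' @param burst optional list `(start, end, amplitude, freq)` describing a
#'   noise burst (seconds, seconds, mm, Hz) added by [add_noise_burst()].
#' @param duration recording length (s).
#' @param dt sampling interval (s).
#' @param seed integer seed; the generator is a deterministic function of
#'   the full parameter set including the seed.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(baseline = 0, amplitude = 10, period = 4,
                         shape_exponent = 2, phase = 0,
                         amp_jitter = 0, period_jitter = 0,
                         noise_sd = 0, drift_rate = 0,
                         drift_mode = c("linear", "random_walk"),
                         burst = NULL, duration = 60, dt = 0.03, seed = 1L) {
  drift_mode <- match.arg(drift_mode)
  shape_exponent <- as.integer(shape_exponent)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (period <= 0) stop("`period` must be > 0", call. = FALSE)
  if (shape_exponent < 1L) stop("`shape_exponent` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (amp_jitter < 0 || period_jitter < 0) {
    stop("jitters must be >= 0", call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (!is.null(burst)) {
    need <- c("start", "end", "amplitude", "freq")
    if (!all(need %in% names(burst))) {
      stop("`burst` needs fields start, end, amplitude, freq", call. = FALSE)
    }
  }
  structure(list(baseline = baseline, amplitude = amplitude, period = period,
                 shape_exponent = shape_exponent, phase = phase,
                 amp_jitter = amp_jitter, period_jitter = period_jitter,
                 noise_sd = noise_sd, drift_rate = drift_rate,
                 drift_mode = drift_mode, burst = burst,
                 duration = duration, dt = dt, seed = as.integer(seed)),
            class = "synth_params")
}

# run code with a private seeded RNG stream, leaving the caller's RNG
# state untouched
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic respiratory signal
#'
#' Deterministic function of its [synth_params()] (including the seed).
#' Period and amplitude jitter are drawn once per breathing cycle from a
#' single seeded stream; within a cycle the amplitude is interpolated
#' linearly towards the next cycle's amplitude so the waveform stays
#' continuous. Drift, white noise and the optional burst are then added.
#'
#' @param params a [synth_params()].
#' @return A [resp_signal()] of `duration_to_points(duration, dt)` samples.
#' @examples
#' sig <- generate_signal(synth_preset("phantom"))
#' length(sig) # 667
#' @export
generate_signal <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  M <- duration_to_points(params$duration, params$dt)
  tt <- (seq_len(M) - 1) * params$dt
  with_local_seed(params$seed, {
    # enough jittered cycles to cover the recording with margin
    n_cyc <- ceiling(params$duration / params$period * 2) + 5
    T_c <- params$period *
      pmax(0.1, 1 + stats::rnorm(n_cyc, 0, params$period_jitter))
    A_c <- params$amplitude *
      pmax(0, 1 + stats::rnorm(n_cyc + 1, 0, params$amp_jitter))
    bounds <- cumsum(c(0, T_c))
    if (bounds[n_cyc + 1] < params$duration) {
      stop("internal error: jittered cycles did not cover the duration",
           call. = FALSE)
    }
    cyc <- findInterval(tt, bounds) # cycle index per sample, 1-based
    frac <- (tt - bounds[cyc]) / T_c[cyc]
    A_loc <- A_c[cyc] + (A_c[cyc + 1] - A_c[cyc]) * frac
    z <- params$baseline +
      A_loc * cos(pi * frac + params$phase)^(2L * params$shape_exponent)
    z <- z + switch(params$drift_mode,
      linear = params$drift_rate * tt,
      random_walk = cumsum(stats::rnorm(M, 0, params$drift_rate *
                                             sqrt(params$dt)))
    )
    if (params$noise_sd > 0) {
      z <- z + stats::rnorm(M, 0, params$noise_sd)
    }
    sig <- resp_signal(z, dt = params$dt)
    if (!is.null(params$burst)) {
      b <- params$burst
      sig <- add_noise_burst(sig, b$start, b$end, b$amplitude, b$freq,
                             seed = params$seed)
    }
    sig
  })
}

#' Synthetic-signal presets
#'
#' Named parameter sets spanning the regimes the pipeline is exercised on:
#'
#' * `"phantom"` — perfectly regular motion (A = 10 mm, T = 4 s, 20 s
#'   recording, no jitter/noise/drift), as from a motion phantom.
#' * `"volunteer_regular"` — quasi-periodic quiet breathing (A = 8 mm,
#'   T = 3.5 s, 5%/4% amplitude/period jitter per cycle, 0.2 mm white
#'   noise, 120 s).
#' * `"volunteer_irregular"` — strongly irregular breathing (20%/15%
#'   jitter, 0.3 mm noise), the regime where nearest-neighbour prediction
#'   degrades.
#' * `"volunteer_drift"` — regular breathing plus 0.05 mm/s linear
#'   baseline drift, the known failure mode of fixed-threshold gating.
#'
#' @param name preset name.
#' @param seed seed stored in the returned parameters.
#' @return A [synth_params()].
#' @export
synth_preset <- function(name, seed = 1L) {
  switch(name,
    phantom = synth_params(baseline = 0, amplitude = 10, period = 4,
                           duration = 20, dt = 0.03, seed = seed),
    volunteer_regular = synth_params(baseline = 0, amplitude = 8,
                                     period = 3.5, amp_jitter = 0.05,
                                     period_jitter = 0.04, noise_sd = 0.2,
                                     duration = 120, dt = 0.03, seed = seed),
    volunteer_irregular = synth_params(baseline = 0, amplitude = 8,
                                       period = 3.2, amp_jitter = 0.20,
                                       period_jitter = 0.15, noise_sd = 0.3,
                                       duration = 120, dt = 0.03,
                                       seed = seed),
    volunteer_drift = synth_params(baseline = 0, amplitude = 8,
                                   period = 3.5, amp_jitter = 0.05,
                                   period_jitter = 0.04, noise_sd = 0.2,
                                   drift_rate = 0.05, duration = 120,
                                   dt = 0.03, seed = seed),
    stop("unknown preset: ", name, call. = FALSE)
  )
}

#' Add a high-frequency noise burst to a signal
#'
#' Adds `amplitude * sin(2*pi*freq*(t - start) + phi)`, with `phi` drawn
#' once from the seeded stream, to exactly the samples whose time lies in
#' `[start, end)`; all other samples are untouched. Bursts on disjoint
#' intervals commute.
#'
#' @param signal a [resp_signal()].
#' @param start,end burst interval in seconds, `0 <= start < end <=`
#'   recording length.
#' @param amplitude burst amplitude (mm).
#' @param freq burst frequency (Hz); choose above the smoothing cutoff for
#'   the burst to be removable.
#' @param seed seed for the burst phase.
#' @return The perturbed [resp_signal()].
#' @export
add_noise_burst <- function(signal, start, end, amplitude, freq, seed = 1L) {
  stopifnot(inherits(signal, "resp_signal"))
  M <- length(signal$values)
  if (!(start >= 0 && start < end && end <= M * signal$dt)) {
    stop("need 0 <= start < end <= recording length", call. = FALSE)
  }
  # samples with 0-based index in [ceil(start/dt), ceil(end/dt))
  i0 <- seconds_to_points(start, signal$dt)
  i1 <- seconds_to_points(end, signal$dt)
  if (i1 <= i0) return(signal)
  idx <- (i0 + 1L):min(i1, M)
  phi <- with_local_seed(seed, stats::runif(1, 0, 2 * pi))
  t_rel <- (idx - 1) * signal$dt - start
  signal$values[idx] <- signal$values[idx] +
    amplitude * sin(2 * pi * freq * t_rel + phi)
  signal
}
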