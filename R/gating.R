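#' Sign-sum statistic of a predicted amplitude tuple against a threshold
#'
#' `sum(sign(a_k - beta))` over the tuple: each predicted sample votes -1
#' if below threshold, +1 if above, 0 if exactly at it. A negative total
#' means the majority of the tuple lies below the gating threshold.
#'
#' @param a numeric tuple of predicted amplitudes (mm).
#' @param beta gating threshold (mm).
#' @return Integer in `[-length(a), length(a)]`.
#' @export
sign_sum <- function(a, beta) {
  if (length(a) == 0L) stop("`a` must be non-empty", call. = FALSE)
  as.integer(sum(sign(a - beta)))
}

#' Prediction-based gating decision
#'
#' Decides the desired beam state from two predicted tuples: `pred_on`
#' spans the `2*m1 + 1` samples centred on the execution time of a gate-on
#' command issued now, `pred_off` the `2*m0 + 1` samples centred on a
#' gate-off execution. Each tuple votes via [sign_sum()]; a negative vote
#' means "mostly below threshold", i.e. beam should be on at that
#' execution time.
#'
#' When `m1 >= m0` the two votes are combined with OR (gate on if either
#' horizon favours it); when `m1 < m0`, with AND.
#'
#' @param pred_on predicted tuple of length `2*m1 + 1`.
#' @param pred_off predicted tuple of length `2*m0 + 1`.
#' @param beta gating threshold (mm).
#' @param m1 gate-on latency in points.
#' @param m0 gate-off latency in points.
#' @return Desired beam state, `0L` or `1L`.
#' @export
gate_decision <- function(pred_on, pred_off, beta, m1, m0) {
  m1 <- as.integer(m1); m0 <- as.integer(m0)
  if (m1 < 0L || m0 < 0L) stop("latencies must be >= 0", call. = FALSE)
  if (length(pred_on) != 2L * m1 + 1L) {
    stop("`pred_on` must have length 2*m1 + 1", call. = FALSE)
  }
  if (length(pred_off) != 2L * m0 + 1L) {
    stop("`pred_off` must have length 2*m0 + 1", call. = FALSE)
  }
  on_vote <- sign_sum(pred_on, beta) < 0L
  off_vote <- sign_sum(pred_off, beta) < 0L
  if (m1 >= m0) as.integer(on_vote || off_vote)
  else as.integer(on_vote && off_vote)
}

#' Apply gate on/off latency to a desired beam-state sequence
#'
#' Edge-triggered command model: whenever the desired state differs from
#' the last issued command, a new command is issued at that index. An
#' on-command issued at `t` executes at `t + m1`, an off-command at
#' `t + m0`. The realized state at `j` is set by the command with the
#' latest execution time `<= j`; ties between execution times are won by
#' the later-issued command. Before any command executes the realized
#' state is `initial_state`.
#'
#' @param desired integer vector of desired states (0/1), one per sample.
#' @param m1 gate-on latency in points.
#' @param m0 gate-off latency in points.
#' @param initial_state beam state before any command executes (default
#'   off).
#' @return Integer vector of realized states, same length as `desired`.
#' @examples
#' apply_latency(c(0, 0, 1, 1, 1, 0, 0, 0), m1 = 2, m0 = 1)
#' # 0 0 0 0 1 1 0 0
#' @export
apply_latency <- function(desired, m1, m0, initial_state = 0L) {
  desired <- as.integer(desired)
  if (anyNA(desired) || any(desired != 0L & desired != 1L)) {
    stop("`desired` must be a 0/1 sequence", call. = FALSE)
  }
  m1 <- as.integer(m1); m0 <- as.integer(m0)
  if (m1 < 0L || m0 < 0L) stop("latencies must be >= 0", call. = FALSE)
  initial_state <- as.integer(initial_state)
  M <- length(desired)
  # issue a command at each index where the desired state departs from the
  # last command sent (not from the realized state)
  last_cmd <- initial_state
  exec_t <- integer(0)
  cmd <- integer(0)
  for (t in seq_len(M)) {
    if (desired[t] != last_cmd) {
      last_cmd <- desired[t]
      exec_t <- c(exec_t, t + if (last_cmd == 1L) m1 else m0)
      cmd <- c(cmd, last_cmd)
    }
  }
  realized <- rep(initial_state, M)
  # stable sort by execution time keeps issue order among ties, so the
  # later-issued command is applied last and wins
  for (i in order(exec_t)) {
    if (exec_t[i] <= M) realized[exec_t[i]:M] <- cmd[i]
  }
  realized
}

#' Gating simulation configuration
#'
#' @param m1 gate-on latency in points (see [latency_to_points()]).
#' @param m0 gate-off latency in points.
#' @param N learning-window length in points.
#' @param n history length in points.
#' @param beta gating threshold in mm, or `NULL` to use the median of the
#'   first `N` samples ([gating_threshold()]).
#' @param smoothing a [smoothing_config()] for the learning windows of the
#'   predictive simulator, or `NULL`.
#' @param initial_state beam state before the first command executes.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(m1, m0, N, n, beta = NULL, smoothing = NULL,
                          initial_state = 0L) {
  m1 <- as.integer(m1); m0 <- as.integer(m0)
  N <- as.integer(N); n <- as.integer(n)
  if (m1 < 0L || m0 < 0L) stop("latencies must be >= 0", call. = FALSE)
  if (N < 1L || n < 1L) stop("`N` and `n` must be positive", call. = FALSE)
  if (n + max(2L * m1 + 1L, 2L * m0 + 1L) > N) {
    stop("need n + max(2*m1 + 1, 2*m0 + 1) <= N for a non-empty learning set",
         call. = FALSE)
  }
  if (!is.null(smoothing) && !inherits(smoothing, "smoothing_config")) {
    stop("`smoothing` must be a smoothing_config or NULL", call. = FALSE)
  }
  structure(list(m1 = m1, m0 = m0, N = N, n = n, beta = beta,
                 smoothing = smoothing,
                 initial_state = as.integer(initial_state)),
            class = "gating_config")
}

#' Construct a gate trace
#'
#' Per-sample realized beam states plus the scored index set
#' `S = {N + n + m1, ..., M}` (1-based) over which [gating_error()] is
#' evaluated. Normally produced by the simulators; the constructor is
#' exported so traces can be built directly.
#'
#' @param states integer vector of realized beam states (0/1).
#' @param scored integer vector of scored sample indices (1-based).
#' @param beta gating threshold (mm) used to drive the trace.
#' @param mode label, e.g. `"conventional"` or `"predictive"`.
#' @return An object of class `gate_trace` with `states`, `scored`,
#'   `on_set`, `off_set`, `beta`, `mode`.
#' @export
gate_trace <- function(states, scored, beta, mode = "custom") {
  states <- as.integer(states)
  scored <- as.integer(scored)
  if (length(scored) == 0L) stop("scored set must be non-empty", call. = FALSE)
  if (any(scored < 1L | scored > length(states))) {
    stop("scored indices out of range", call. = FALSE)
  }
  on <- scored[states[scored] == 1L]
  structure(list(states = states, scored = scored,
                 on_set = on, off_set = setdiff(scored, on),
                 beta = beta, mode = mode),
            class = "gate_trace")
}

#' @export
print.gate_trace <- function(x, ...) {
  cat(sprintf(
    "<gate_trace> %s: %d samples, %d scored, duty cycle %.1f%% (beta = %.3f mm)\n",
    x$mode, length(x$states), length(x$scored),
    100 * length(x$on_set) / length(x$scored), x$beta))
  invisible(x)
}

#' Simulate conventional threshold-triggered gating with latency
#'
#' The desired beam state at each sample is `1` iff the amplitude is
#' strictly below the threshold; gate commands are issued at threshold
#' crossings and execute after the configured latencies
#' ([apply_latency()]). This reproduces the gating-window shifts that
#' motivate prediction-based compensation: each realized window starts
#' `m1` points late and ends `m0` points late.
#'
#' @param signal a [resp_signal()].
#' @param config a [gating_config()].
#' @return A [gate_trace()] scored over `S = {N + n + m1, ..., M}`.
#' @export
simulate_conventional <- function(signal, config) {
  stopifnot(inherits(signal, "resp_signal"), inherits(config, "gating_config"))
  x <- signal$values
  M <- length(x)
  warm <- config$N + config$n + config$m1
  if (M < warm) {
    stop("signal too short: need at least N + n + m1 samples", call. = FALSE)
  }
  beta <- config$beta %||% gating_threshold(signal, config$N)
  desired <- as.integer(x < beta)
  realized <- apply_latency(desired, config$m1, config$m0,
                            config$initial_state)
  gate_trace(realized, scored = warm:M, beta = beta, mode = "conventional")
}

#' Simulate prediction-based gating (pRGRT) with latency
#'
#' At each decision time `t` past the warm-up, the `N` raw samples ending
#' at `t - n - 1` are smoothed and sliced into two learning sets sharing
#' the same `n`-point histories: one with `2*m1 + 1`-point futures
#' (spanning the execution time of an on-command issued at `t`) and one
#' with `2*m0 + 1`-point futures (off-command). Nearest-neighbour lookup
#' with the raw recent history yields the two predicted tuples, and
#' [gate_decision()] sets the desired state. Commands then incur the same
#' latencies as the conventional simulator — the compensation comes
#' entirely from the decision looking ahead to the execution time.
#'
#' During warm-up (`t <= N + n`) the desired state is off; the scored set
#' excludes the warm-up, so the gating error is unaffected.
#'
#' @param signal a [resp_signal()].
#' @param config a [gating_config()].
#' @return A [gate_trace()] scored over `S = {N + n + m1, ..., M}`.
#' @export
simulate_predictive <- function(signal, config) {
  stopifnot(inherits(signal, "resp_signal"), inherits(config, "gating_config"))
  x <- signal$values
  M <- length(x)
  N <- config$N; n <- config$n
  m1 <- config$m1; m0 <- config$m0
  warm <- N + n + m1
  if (M < warm) {
    stop("signal too short: need at least N + n + m1 samples", call. = FALSE)
  }
  beta <- config$beta %||% gating_threshold(signal, N)
  alpha <- resolve_alpha(config$smoothing, N, signal$dt)
  ma <- 2L * m1 + 1L
  mb <- 2L * m0 + 1L
  K1 <- N - n - ma + 1L
  K0 <- N - n - mb + 1L
  Kmax <- max(K1, K0)
  hidx <- outer(seq_len(Kmax), 0:(n - 1L), "+")
  desired <- integer(M) # off during warm-up t <= N + n
  for (t in (N + n + 1L):M) {
    win <- x[(t - n - N):(t - n - 1L)]
    sw <- if (is.null(alpha)) win else smooth_window(win, alpha)
    th <- x[(t - n):(t - 1L)]
    H <- sw[hidx]; dim(H) <- dim(hidx)
    d2 <- rowSums((H - rep(th, each = Kmax))^2)
    d1 <- d2[seq_len(K1)]
    p1 <- max(which(d1 == min(d1)))
    d0 <- d2[seq_len(K0)]
    p0 <- max(which(d0 == min(d0)))
    pred_on <- sw[(p1 + n):(p1 + n + ma - 1L)]
    pred_off <- sw[(p0 + n):(p0 + n + mb - 1L)]
    desired[t] <- gate_decision(pred_on, pred_off, beta, m1, m0)
  }
  realized <- apply_latency(desired, m1, m0, config$initial_state)
  gate_trace(realized, scored = warm:M, beta = beta, mode = "predictive")
}

#' Normalized gating error (nErr)
#'
#' Mean, over the scored index set, of the amplitude excess above
#' threshold while the beam is on plus the deficit below threshold while
#' it is off: `mean( (x_j - beta)^+ [on] + (x_j - beta)^- [off] )`, in mm.
#' Zero iff the beam is on exactly when the amplitude is below threshold
#' (ideal gating); always non-negative; invariant under a joint shift of
#' signal and threshold.
#'
#' @param signal a [resp_signal()].
#' @param trace a [gate_trace()].
#' @param beta threshold; defaults to the one stored in the trace.
#' @return nErr in mm.
#' @export
gating_error <- function(signal, trace, beta = NULL) {
  stopifnot(inherits(signal, "resp_signal"), inherits(trace, "gate_trace"))
  beta <- beta %||% trace$beta
  S <- trace$scored
  if (any(S > length(signal$values))) {
    stop("trace scored set exceeds signal length", call. = FALSE)
  }
  dev <- signal$values[S] - beta
  on <- trace$states[S] == 1L
  mean(ifelse(on, pmax(dev, 0), pmax(-dev, 0)))
}
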