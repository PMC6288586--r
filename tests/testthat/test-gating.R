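test_that("sign-sum votes per sample with zero at the threshold", {
  expect_identical(sign_sum(c(2, 2, 2), 2), 0L)
  expect_identical(sign_sum(rep(-1, 5), 0), -5L)
  expect_identical(sign_sum(rep(9, 4), 0), 4L)
  expect_identical(sign_sum(c(-1, -2, 3), 0), -1L)
  expect_error(sign_sum(numeric(0), 0), "non-empty")
})

test_that("gate decision combines votes with OR (m1 >= m0) or AND (m1 < m0)", {
  below <- function(k) rep(-1, k) # all below beta = 0
  above <- function(k) rep(1, k)
  # both horizons below: on in both orderings
  expect_identical(gate_decision(below(5), below(3), 0, 2, 1), 1L)
  expect_identical(gate_decision(below(3), below(5), 0, 1, 2), 1L)
  # both above: off in both orderings
  expect_identical(gate_decision(above(5), above(3), 0, 2, 1), 0L)
  expect_identical(gate_decision(above(3), above(5), 0, 1, 2), 0L)
  # split votes: OR turns on, AND stays off
  expect_identical(gate_decision(below(5), above(3), 0, 2, 1), 1L)
  expect_identical(gate_decision(below(3), above(5), 0, 1, 2), 0L)
  # exactly at threshold: vote 0, not < 0, beam off
  expect_identical(gate_decision(rep(0, 5), rep(0, 3), 0, 2, 1), 0L)
  expect_identical(gate_decision(rep(0, 3), rep(0, 5), 0, 1, 2), 0L)
  expect_error(gate_decision(below(4), below(3), 0, 2, 1), "2\\*m1")
  expect_error(gate_decision(below(5), below(4), 0, 2, 1), "2\\*m0")
})

test_that("with m1 = m0 the OR form agrees with AND when the votes agree", {
  # enumerate all sign patterns of two 3-point windows
  vals <- c(-1, 0, 1)
  grid <- expand.grid(a1 = vals, a2 = vals, a3 = vals,
                      b1 = vals, b2 = vals, b3 = vals)
  for (r in seq_len(nrow(grid))) {
    on_tuple <- as.numeric(grid[r, 1:3])
    off_tuple <- as.numeric(grid[r, 4:6])
    v1 <- sign_sum(on_tuple, 0) < 0
    v0 <- sign_sum(off_tuple, 0) < 0
    or_rule <- gate_decision(on_tuple, off_tuple, 0, 1, 1)
    if (v1 == v0) expect_identical(or_rule, as.integer(v1 && v0))
  }
})

test_that("latency application matches hand-stepped command traces", {
  expect_identical(apply_latency(c(0, 0, 1, 1, 1, 0, 0, 0), 2, 1),
                   c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L))
  # zero latency reproduces the desired sequence
  d <- c(0, 1, 1, 0, 1, 0)
  expect_identical(apply_latency(d, 0, 0), as.integer(d))
  # constant desired: no transition if it equals the initial state
  expect_identical(apply_latency(rep(0, 6), 3, 2), rep(0L, 6))
  # otherwise a single delayed switch
  expect_identical(apply_latency(rep(1, 6), 3, 2), c(0L, 0L, 0L, 1L, 1L, 1L))
  # reversed ordering: on-command overtaken by a faster off-command
  # on issued at t=2 executes t=5; off issued at t=3 executes t=4;
  # the on execution is latest from t=5 on, so the beam latches on
  expect_identical(apply_latency(c(0, 1, 0, 0, 0, 0), 3, 1),
                   c(0L, 0L, 0L, 0L, 1L, 1L))
  expect_error(apply_latency(c(0, 2), 1, 1), "0/1")
})

test_that("realized state deviates only near well-separated transitions", {
  set.seed(17)
  for (trial in 1:10) {
    m1 <- sample(0:4, 1); m0 <- sample(0:4, 1)
    # square wave with half-period comfortably above m1 + m0
    half <- m1 + m0 + sample(3:6, 1)
    d <- rep(rep(c(0L, 1L), 6), each = half)
    r <- apply_latency(d, m1, m0)
    mismatch <- which(r != d)
    transitions <- which(diff(d) != 0) + 1L
    for (j in mismatch) {
      gap <- min(abs(j - transitions))
      expect_lte(gap, max(m1, m0) - 1L)
    }
  }
})

test_that("conventional simulation shifts windows by the latencies", {
  # regular crossing pattern: threshold 0.5, clean square-ish signal
  x <- rep(rep(c(0, 1), 10), each = 20) # 20-point half-cycles
  sig <- resp_signal(x, dt = 0.03)
  cfg <- gating_config(m1 = 2, m0 = 1, N = 40, n = 5, beta = 0.5)
  tr <- simulate_conventional(sig, cfg)
  ideal <- as.integer(x < 0.5)
  # realized equals ideal shifted: on-starts 2 late, on-ends 1 late
  expected <- apply_latency(ideal, 2, 1)
  expect_identical(tr$states, expected)
  starts <- which(diff(tr$states) == 1) + 1L
  ideal_starts <- which(diff(ideal) == 1) + 1L
  expect_identical(starts[starts > 40], (ideal_starts + 2L)[ideal_starts > 40])
})

test_that("conventional simulation with zero latency is ideal", {
  sig <- generate_signal(synth_preset("phantom"))
  cfg <- gating_config(m1 = 0, m0 = 0, N = 100, n = 10)
  tr <- simulate_conventional(sig, cfg)
  expect_identical(tr$states[tr$scored],
                   as.integer(sig$values < tr$beta)[tr$scored])
  expect_equal(gating_error(sig, tr), 0)
})

test_that("a signal entirely above threshold never turns the beam on", {
  sig <- resp_signal(5 + abs(sin(seq(0, 20, length.out = 300))), dt = 0.03)
  cfg <- gating_config(m1 = 2, m0 = 1, N = 50, n = 5, beta = 1)
  tr <- simulate_conventional(sig, cfg)
  expect_true(all(tr$states == 0L))
})

test_that("gate trace bookkeeping partitions the scored set", {
  sig <- generate_signal(synth_preset("phantom"))
  cfg <- gating_config(m1 = 3, m0 = 1, N = 100, n = 10)
  tr <- simulate_conventional(sig, cfg)
  expect_equal(tr$scored, (100 + 10 + 3):667)
  expect_equal(length(tr$scored), 667 - 100 - 10 - 3 + 1)
  expect_setequal(c(tr$on_set, tr$off_set), tr$scored)
  expect_length(intersect(tr$on_set, tr$off_set), 0)
})

test_that("nErr matches its defining formula and invariances", {
  # hand-computed example over a 4-point scored set
  sig <- resp_signal(c(1, -1, 2, -2), dt = 0.03)
  tr <- gate_trace(states = c(1L, 1L, 0L, 0L), scored = 1:4, beta = 0)
  expect_equal(gating_error(sig, tr), 0.75)
  # beam always on under an all-below signal: zero error
  sig2 <- resp_signal(rep(-3, 10), dt = 0.03)
  tr2 <- gate_trace(rep(1L, 10), scored = 3:10, beta = 0)
  expect_equal(gating_error(sig2, tr2), 0)
  # joint shift of signal and threshold leaves nErr unchanged
  set.seed(31)
  v <- rnorm(50); st <- sample(0:1, 50, replace = TRUE)
  for (c in c(-5, 2.5)) {
    e0 <- gating_error(resp_signal(v, 0.03),
                       gate_trace(st, 10:50, beta = 0.3))
    e1 <- gating_error(resp_signal(v + c, 0.03),
                       gate_trace(st, 10:50, beta = 0.3 + c))
    expect_equal(e1, e0)
    expect_gte(e0, 0)
  }
})

test_that("predictive simulation handles the degenerate regimes", {
  # constant signal below threshold: beam permanently on after warm-up.
  # The first decision (t = N + n + 1) executes its on-command at
  # t + m1 = N + n + m1 + 1, one point after the scored set opens, so
  # exactly one scored sample is unavoidably pre-execution.
  sig <- resp_signal(rep(-1, 300), dt = 0.03)
  cfg <- gating_config(m1 = 2, m0 = 1, N = 60, n = 5, beta = 0,
                       smoothing = NULL)
  tr <- simulate_predictive(sig, cfg)
  first_exec <- 60 + 5 + 1 + 2
  expect_true(all(tr$states[first_exec:300] == 1L))
  expect_equal(gating_error(sig, tr), 1 / length(tr$scored))
  # zero latency: decision reduces to "predicted current sample below beta";
  # on a noiseless periodic signal the prediction is exact and gating is
  # ideal everywhere a decision exists
  sigp <- generate_signal(synth_params(amplitude = 10, period = 3.6,
                                       duration = 18, dt = 0.03))
  cfg0 <- gating_config(m1 = 0, m0 = 0, N = 300, n = 20, smoothing = NULL)
  tr0 <- simulate_predictive(sigp, cfg0)
  decided <- gate_trace(tr0$states, scored = (300 + 20 + 1):length(sigp),
                        beta = tr0$beta)
  expect_equal(gating_error(sigp, decided), 0)
  expect_identical(tr0$states[decided$scored],
                   as.integer(sigp$values < tr0$beta)[decided$scored])
})

test_that("predictive gating beats conventional on clean periodic motion", {
  sig <- generate_signal(synth_params(amplitude = 10, period = 3.6,
                                      duration = 36, dt = 0.03))
  cfg <- gating_config(m1 = 12, m0 = 3, N = 400, n = 30, smoothing = NULL)
  conv <- simulate_conventional(sig, cfg)
  pred <- simulate_predictive(sig, cfg)
  e_conv <- gating_error(sig, conv)
  e_pred <- gating_error(sig, pred)
  expect_gt(e_conv, 0) # latency hurts the conventional arm
  expect_lt(e_pred, e_conv)
  # near-ideal compensation on a perfectly periodic signal
  expect_lt(e_pred, 0.05 * e_conv)
})

test_that("gating config rejects windows too small for the horizons", {
  expect_error(gating_config(m1 = 12, m0 = 3, N = 80, n = 60), "non-empty")
  expect_s3_class(gating_config(m1 = 12, m0 = 3, N = 90, n = 60),
                  "gating_config")
  expect_error(gating_config(m1 = -1, m0 = 0, N = 100, n = 10), ">= 0")
})

test_that("baseline drift wrecks conventional fixed-threshold gating", {
  smo <- smoothing_config(cutoff_hz = 1)
  prof <- latency_profile("abches")
  drift <- generate_signal(synth_preset("volunteer_drift", seed = 2))
  flat <- generate_signal(synth_preset("volunteer_regular", seed = 2))
  cfg <- gating_config(m1 = prof$m1, m0 = prof$m0, N = 1500, n = 60,
                       smoothing = smo)
  e_drift <- gating_error(drift, simulate_conventional(drift, cfg))
  e_flat <- gating_error(flat, simulate_conventional(flat, cfg))
  expect_gt(e_drift, 2 * e_flat)
  # the predictive arm may or may not retain its advantage under drift;
  # it must at least produce a finite, non-negative error
  e_pred <- gating_error(drift, simulate_predictive(drift, cfg))
  expect_true(is.finite(e_pred) && e_pred >= 0)
})
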