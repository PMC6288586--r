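---
title: "Prediction-based compensation of gate latency in respiratory-gated radiotherapy"
author: "respgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction-based compensation of gate latency in respiratory-gated radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respgate)
```

## The problem

In amplitude-based respiratory-gated radiotherapy (RGRT) the treatment beam
is switched on only while the breathing amplitude $x_t$ (mm, sampled every
$\Delta\tau$ seconds) is below a gating threshold $\beta$ — during the
exhalation plateau, when the tumour is closest to its reference position.
Commercial gating systems need a few hundred milliseconds between detecting
a threshold crossing and actually switching the beam: published gate-on /
gate-off latencies range from roughly 60 ms to 850 ms depending on the
monitor/linac combination (`latency_profiles()`). With threshold-triggered
("conventional") gating, every realized gating window therefore starts
$m_1$ samples late and ends $m_0$ samples late, where $m_1 = \lceil
\text{delay}_{\mathrm{on}}/\Delta\tau \rceil$ and similarly $m_0$. The beam
is on while the amplitude is already rising, and off while it is still low.

respgate implements a compensation strategy: predict the amplitudes around
the *execution* time of a command issued now, and decide the command from
the prediction rather than from the current sample.

## Pipeline

### Low-pass smoothing

Learning data are denoised with a windowed finite-Fourier low-pass
operator: multiply the $N$-point window elementwise by Hamming weights
$w_k = 0.54 - 0.46\cos(2\pi k/(N-1))$, apply the (unnormalized) forward
DFT, zero every coefficient $k$ with $|k - N/2| < N/2 - \alpha$ (a strict
inequality; boundary bins are kept), invert the DFT (with the $1/N$
factor), take the real part, and divide the Hamming weights back out. The
mask parameter relates to a physical cutoff $f$ in Hz by $\alpha = N
\Delta\tau f$, kept real-valued — the strict inequality consumes
non-integer $\alpha$ without rounding. Since Hamming weights never fall
below 0.08, the inverse window is well-conditioned.

The operator is linear and idempotent, and $\alpha \ge N/2$ makes it the
identity. These algebraic properties, and agreement with a naive
$O(N^2)$ direct-DFT implementation to $10^{-10}$, are asserted in the test
suite. Because the window is multiplied *and later divided* by the Hamming
weights, the operator is not exactly a circular-convolution filter; the
division re-amplifies edge samples (weight 0.08), which is why smoothing a
band-limited signal is only *approximately* the identity and why the
smoothed learning window, not the raw query, is the denoised object.

### Nearest-neighbour multistep prediction

From a smoothed $N$-point window, all $N - n - m + 1$ overlapping pairs of
an $n$-point history and the following $m$-point future are collected into
a learning set. For a query history $\mathbf{x}$, the predictor returns the
future of the history minimizing the Euclidean distance; among exact ties
the *largest* index (most recent pair) wins. This tie rule is part of the
method definition, not an implementation convenience, and is checked
against exhaustive search. Distances are compared as plain floating-point
numbers — no epsilon tolerance — because the largest-index rule already
yields a deterministic answer under any total order.

Serial ("rolling-origin") evaluation rebuilds the learning set at every
time step from the $N$ raw samples ending just before the query history,
smooths it, predicts $m$ steps ahead, and scores only the $m$-th predicted
coordinate against the later observation, summarized as RMSE over all
$M - N - n - m + 1$ trials. The query history is left raw by default
(`smooth_test_history = FALSE`): the decision rule is defined on the raw
recent history, and smoothing the short query with its own Hamming window
would distort its edges; the switch exists for sensitivity analyses.

### Prediction-based gating

At decision time $t$, two learning sets are built from the same smoothed
window: one with futures of length $2m_1 + 1$ (centred, in time, on the
execution instant $t + m_1$ of an on-command issued at $t$) and one with
futures of length $2m_0 + 1$ (off-command, executing at $t + m_0$). Each
predicted tuple votes through the sign-sum statistic $\xi = \sum_k
\mathrm{sgn}(\hat{x}_k - \beta)$: $\xi < 0$ means the majority of the
tuple lies below threshold, i.e. the beam should be on at that execution
time. For $m_1 \ge m_0$ the two votes are combined with OR, for
$m_1 < m_0$ with AND — the asymmetric combination errs on the side of the
slower command. Samples exactly at $\beta$ vote 0 and never switch the
beam on by themselves.

Crucially, the issued commands then incur exactly the same latencies as in
conventional gating; all compensation comes from the decision looking
ahead to the execution time.

### Latency mechanics

Both simulators share one latency model (`apply_latency()`): a command is
issued whenever the desired state differs from the last issued command;
on-commands execute $m_1$ samples after issue, off-commands $m_0$; the
realized state at sample $j$ is set by the command with the latest
execution time $\le j$, ties going to the later-issued command. When
desired transitions are separated by more than $m_1 + m_0$ samples this
reproduces the textbook picture — windows shifted by $m_1$ at the start
and $m_0$ at the end. When they are not (chatter near the threshold), the
model allows an on-command to execute *after* a subsequently issued
off-command, latching the beam on until the next command; this is a real
consequence of asymmetric latencies, affects both arms identically, and is
the mechanism behind the conventional arm's collapse under baseline drift
(below).

### The nErr metric

Gating quality is scored over $S = \{N + n + m_1, \dots, M\}$ (1-based; the
warm-up in which no learning window exists is excluded) as the mean of
$(x_j - \beta)^+$ where the beam is on and $(x_j - \beta)^-$ where it is
off — the average amplitude of "inappropriate irradiation plus missed
irradiation", in mm. Ideal gating scores 0; the metric is invariant under
jointly shifting signal and threshold. $S$ is defined once, with $m_1$ in
its lower bound, and reused for both latency orderings and both arms; its
first sample precedes the earliest possible predictive command execution
by one point, so even a perfect predictor retains a $1/|S|$-scale floor.

## The synthetic generator

Quiet breathing is modelled as $b_0 + A\cos^{2p}(\pi t/T + \varphi)$ with
$p = 2$: an even cosine power spends most of each cycle near the baseline
(the exhalation plateau) with brief inhalation peaks, which is the
qualitative shape of abdominal-wall respiratory traces. Perturbations:

* per-cycle amplitude and period jitter (drawn once per breathing cycle
  from a single seeded stream, so periods stay locally coherent; the
  amplitude is interpolated linearly across the cycle to keep the
  waveform continuous),
* additive white noise,
* linear baseline drift (a random-walk mode exists for stress tests), and
* an optional high-frequency sinusoidal burst confined to a time interval.

Presets: `phantom` ($A = 10$ mm, $T = 4$ s, 20 s, no perturbations — a
motion-phantom recording), `volunteer_regular` ($A = 8$ mm, $T = 3.5$ s,
5%/4% amplitude/period jitter, 0.2 mm noise, 120 s), `volunteer_irregular`
(20%/15% jitter, 0.3 mm noise), and `volunteer_drift` (regular plus
0.05 mm/s drift). The volunteer values were fixed once as representative
of adult quiet breathing (period 3–5 s, excursion 5–15 mm, sub-half-mm
sensor noise); they are this package's choices, not measured values. The
generator emulates amplitude statistics only — it has no cardiac
superposition, no hysteresis between inhale and exhale shape, and no
long-range autocorrelation in the jitter — so passing tests demonstrate
correct mechanics and behaviour on quasi-periodic signals, not clinical
performance.

## Worked example

```{r example, eval = FALSE}
sig <- generate_signal(synth_preset("volunteer_regular", seed = 1))
prof <- latency_profile("abches", dt = sig$dt)
cfg <- gating_config(m1 = prof$m1, m0 = prof$m0, N = 1500, n = 60,
                     smoothing = smoothing_config(cutoff_hz = 1))
gating_error(sig, simulate_conventional(sig, cfg)) # 0.177 mm
gating_error(sig, simulate_predictive(sig, cfg))   # 0.005 mm
```

Across five seeds of `volunteer_regular` the predictive arm scores a lower
nErr than the conventional arm for all five, under both the Abches-like
ordering ($m_1 = 12 \ge m_0 = 3$) and the AlignRT-like ordering
($m_1 = 12 < m_0 = 18$); `scripts/acceptance.R` recomputes this.

## Numerical and design choices

* **Seconds to points.** All conversions use the ceiling, with a $10^{-9}$
  subtraction guarding against binary floating-point pushing exact
  multiples (0.3/0.03) just above the integer. Ceiling is the only rule
  consistent with a command that cannot execute before its delay elapses.
* **Threshold.** $\beta$ defaults to the median of the first $N$ samples;
  for even counts, the mean of the two central order statistics. It is a
  robust location estimate of the early exhalation plateau.
* **Scaled problem sizes.** The test suite and acceptance script run the
  serial-prediction protocol at $M = 2000$, $N = 1000$, $n = 60$, $m = 10$
  and the gating simulations at $M = 4000$, $N = 1500$, $n = 60$ — large
  enough that the learning window holds many breathing cycles (the regime
  the method needs), small enough to iterate on quickly. The full-scale
  protocol ($M = 10000$, $N = 4000$, $n = 100$) runs unchanged through the
  same functions on imported recordings.
* **Warm-up.** The predictive simulator keeps the beam off while $t \le
  N + n$; the scored set excludes almost all of this region by
  construction.
* **Degenerate inputs.** Constant windows produce all-tied learning sets
  (resolved by the largest-index rule); signals entirely above threshold
  never issue an on-command; NaN/Inf amplitudes are rejected at ingestion
  rather than interpolated; irregular time grids are accepted with a
  warning and treated as exactly uniform at the median step, mirroring the
  fixed-$\Delta\tau$ assumption under which the method is defined.

## Known limitations

* The conventional arm is sensitive to command chatter when noise crosses
  the threshold, and under baseline drift with a fixed threshold it
  degrades severely (the drift preset produces conventional nErr near 4 mm
  against ~0.2 mm without drift). The predictive arm, whose smoothed
  learning sets suppress chatter, tracks the fixed threshold well even
  under linear drift — but a fixed threshold on a drifting baseline is
  clinically questionable regardless of the controller, and real drifting
  recordings combine drift with irregularity that the linear-drift preset
  does not emulate, so no claim is made that prediction rescues drifting
  signals in practice.
* Nearest-neighbour lookup assumes the learning window contains a segment
  resembling the current history: strongly irregular breathing
  (`volunteer_irregular`) degrades prediction and hence gating.
* Only amplitude-based exhalation gating is modelled; phase-based gating,
  inhalation gating, duty-cycle optimisation and dose calculation are out
  of scope.
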