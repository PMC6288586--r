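Package: respgate
Title: Prediction-Based Gate Latency Compensation for Respiratory-Gated
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating and compensating gate on/off latency in
    amplitude-based respiratory-gated radiotherapy (RGRT). Provides finite
    Fourier low-pass smoothing of respiratory signals with a Hamming window,
    nearest-neighbour multistep-ahead prediction from sliding learning sets,
    a prediction-based gating rule with sign-sum voting over the latency
    horizon, latency-aware simulators for conventional and prediction-based
    gating, the nErr gating-error and RMSE prediction-error metrics, and a
    seeded generator of synthetic respiratory signals (regular phantom
    motion, quasi-periodic volunteer breathing, noise bursts, baseline
    drift) so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
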