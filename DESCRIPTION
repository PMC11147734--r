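Package: scanlock
Title: Resonant-Scanner Jitter Simulation and Phase-Locked Sampling Metrology
Version: 0.1.0
Authors@R:
    person("scanlock", "developers", email = "scanlock@example.org",
           role = c("aut", "cre"))
Description: Simulates the timing and pointing errors of resonant-scanning
    laser microscopes: stochastic mirror jitter, electronic position-feedback
    jitter, slow-axis wobble and crosstalk, and the bounded synchronization
    jitter that arises when the pixel sampling clock free-runs relative to
    the scanner. A discrete-time zero-delay phase-locked loop (PLL) model
    denoises the feedback edge series and synthesizes integer-multiple
    sampling clocks, so that phase-locked versus asynchronous acquisition can
    be compared without hardware. A companion metrology suite implements
    subsample edge and peak localization, per-line slit tracking,
    bidirectional (forward/backward) misalignment via cross-correlation,
    jitter power spectral densities, wobble ellipse fitting, intra-cycle
    jitter, and point-spread-function broadening under frame averaging.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
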