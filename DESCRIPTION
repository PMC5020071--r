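Package: mscann
Title: Continuous Attractor Networks with Multiple Short-Term Time Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-dimensional continuous attractor
    neural networks (CANNs) whose dynamics combine short-term facilitation,
    spike-frequency adaptation, and short-term depression of recurrent and
    feedforward synapses on separated time scales. Provides a deterministic
    neural-field integrator on a periodic lattice (FFT-based circular
    convolution, forward Euler), closed-form results for the stationary bump
    and its critical inhibition strength, observables (bump center, plateau
    lifetime, traveling-wave speed, signed tracking separation), experiment
    drivers for persistent activity, adaptation and anticipative tracking,
    phase-diagram sweeps with bisection of regime boundaries, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
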