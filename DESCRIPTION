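Package: peaknet
Title: Peak-Map and Neural-Emulator Stability Analysis for Discrete Lorenz Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and stability-analysis toolkit for discrete Lorenz
    dynamics and Hebbian recurrent network emulators. Integrates the Lorenz
    flow with explicit Euler, classical fourth-order Runge-Kutta and implicit
    midpoint schemes (with adaptive step-doubling control), extracts the
    one-dimensional peak (successor-of-maxima) map, locates periodic orbits
    and classifies their stability through cycle multipliers, estimates
    Lyapunov spectra and Kaplan-Yorke dimensions, simulates the original and
    modified Kropotov-Pakhomov binary neural network with delayed
    Bogdanov-Hebb plasticity and divisive normalization, and analyses a
    continuous-state tanh recurrent operator whose monodromy spectral radius
    is the multidimensional counterpart of the peak-map multiplier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
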