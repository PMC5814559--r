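Package: bubblesteer
Title: Modelling Ultrasound Doppler Propulsion of Oxygen Nanobubbles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physical model of oxygen nanobubbles propelled through a liquid
    by a pulsed-wave Doppler ultrasound beam: primary Bjerknes forcing from a
    harmonic plane pressure wave, buoyancy, and Stokes drag assembled into a
    driven damped first-order equation of motion with a closed-form velocity
    profile v(t) = A*cos(wt) - B*sin(wt) + C*exp(-alpha*t) + v_offset. Includes
    an independent adaptive ODE oracle, nonlinear least-squares fitting of the
    decay model to measured velocity traces, beam-power sweep analysis
    (monotonicity and power-law exponent), exponential-decay profiling of
    bubble penetration depth in tissue sections with baseline significance
    testing, a seeded synthetic-data generator emulating the measured traces
    and depth profiles, and a reproducible configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
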