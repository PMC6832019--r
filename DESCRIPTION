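Package: phageshift
Title: Alternative Stable States and Regime Shifts in Phage-Bacterium
    Ecosystems
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a well-mixed ecosystem in which two
    bacterial species compete for a single limiting nutrient while being
    infected by a shared virulent phage.  Provides the deterministic
    consumer-resource/phage dynamics with a weak species influx floor, an
    event-driven stochastic (Gillespie) simulator on quantized populations,
    closed-form steady states and regime boundaries from zero-net-growth
    isocline geometry, bistability and hysteresis analysis via quasi-static
    nutrient-supply sweeps, and impulsive ("population pulse") control
    experiments including combined phage-plus-competitor therapy and the
    perfect abortive-infection limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
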