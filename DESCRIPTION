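Package: adexfit
Title: Fitting Adaptive Exponential Integrate-and-Fire Models to Cerebellar
    Granule Cell Firing Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the two-variable adaptive exponential
    integrate-and-fire (AdEx) point-neuron model under step and sinusoidal
    current protocols with an adaptive Runge-Kutta-Fehlberg integrator and
    event-localized spike handling; extracts the firing features used to
    characterise cerebellar granule cells (per-cycle burst frequency and
    spiking-resonance curves, mean firing rate and first-spike latency
    under step currents, rheobase, I-F slope, and the subthreshold
    impedance profile); scores candidate parameter sets against
    experimental feature targets with weighted absolute-error fitness
    functions, optionally penalised by cycle-to-cycle burst variability;
    and searches the bounded 10-parameter space with a generational
    evolutionary algorithm (tournament selection, one-point crossover,
    uniform mutation). Bundles the published reference parameter sets and
    experimental target tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
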