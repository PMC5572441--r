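Package: binamr
Title: Binary Neural Associative Memory Benchmark for Spiking Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking spiking neural substrates with the binary
    neural associative memory (BiNAM). Provides balanced sparse pattern
    generation, Willshaw/Palm clipped Hebbian storage and threshold recall,
    information-capacity theory with generalized binomials, translation of
    binary patterns to spike trains (burst and population coding with
    Gaussian jitter), a reference conductance-based leaky integrate-and-fire
    simulator with fixed-step Euler and adaptive Runge-Kutta-Fehlberg
    integration, a fractional-spike-count neuron parameter optimizer, and
    normalized benchmark metrics including an energy-efficiency measure.
    External simulators plug in through a black-box back-end contract based
    on a JSON network description and CSV spike-train exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
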