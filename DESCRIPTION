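Package: wavedecode
Title: Decoding Traveling Cortical Waves with Dendritic Gabor Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation of a hierarchical model of the descending motor
    system in which traveling beta-band waves, generated by a sheet of
    spatially coupled Kuramoto phase oscillators with anisotropic
    inhibitory-surround coupling, are decoded by pyramidal tract neurons
    whose dendritic receptor fields act as spatial Gabor filters. The
    dendritic current drives an Izhikevich-type soma; spikes descend onto
    a leaky integrate-and-fire motor-neuron pool whose output is rendered
    as surface EMG. Includes construction of excitatory/inhibitory
    receptor density surfaces whose signed sum is a target Gabor filter,
    conductance-based dendritic integration under Poisson bombardment,
    orientation tuning curves, spike-train irregularity metrics, and
    Welch-based corticomuscular coherence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
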