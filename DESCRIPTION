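Package: corthal
Title: Corticothalamic Network Simulation of Cortical Synaptic Loss
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a network of delay-coupled corticothalamic neural-mass
    units (excitatory and inhibitory cortical populations plus thalamic
    reticular and relay populations) over a weighted structural connectome,
    and studies the effect of step-wise reductions of excitatory and/or
    inhibitory cortical synaptic coupling on alpha-band (8-13 Hz) power and
    phase-locking-value connectivity. Includes a linearized transfer-function
    spectral oracle, Welch spectral and phase-locking outcome metrics, a
    nested linear mixed-effects stage for post-mortem synapse and neuron
    density tables, and synthetic generators for both the connectome and the
    nested histology data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    igraph,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
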