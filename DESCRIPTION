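Package: vtdp
Title: Vesicle-Timing Dependent Plasticity and the Developmental Release-Mode Switch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Hebbian plasticity driven by the timing of synaptic
    vesicle exocytosis rather than presynaptic spike times. A feed-forward
    network of Poisson presynaptic neurons and leaky integrate-and-fire
    postsynaptic neurons releases vesicles in three modes (spontaneous,
    asynchronous evoked via residual calcium, and synchronous evoked), with
    finite vesicle pools, a pair-based vesicle-timing dependent plasticity
    rule, and homeostatic synaptic scaling. Companion tools implement a
    competitive rate model of pattern imprinting, a developmental schedule
    that maps calcium-sensor expression profiles onto release-mode fractions
    with synaptogenesis and pruning, and pairing-protocol drivers that
    measure the maturation of the spike-timing dependent plasticity curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
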