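Package: synapcomp
Title: Spiking Synaptic Competition and Constraint-Induced Intervention Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulator of activity-dependent synaptic competition
    in a two-layer corticospinal network. Regular-spiking Izhikevich neurons
    are coupled by additive, all-to-all spike-timing-dependent plasticity
    (STDP) synapses with exponential current and weight decay, and driven by
    seeded uniform noise currents. Stage-sequencing protocols reproduce
    injury-induced winner-take-all dominance, its persistence after normal
    input is restored (hysteresis), and its reversal by constraint-induced
    intervention; a rate-based BCM comparator with a sliding modification
    threshold contrasts the two plasticity theories under ocular-dominance
    style deprivation conditions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
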