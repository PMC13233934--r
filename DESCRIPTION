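Package: stasnet
Title: Spatio-Temporal Activity Sequences in Anisotropic Rate Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of spatio-temporal activity sequences
    (STAS) in recurrent firing-rate networks on a toroidal grid.  Networks
    combine a Mexican-hat connectivity kernel with a spatially correlated
    anisotropic shift of excitatory projections, producing a heterogeneous
    in-degree landscape along which activity sequences propagate.  The package
    builds such connectomes, integrates the rate dynamics under Gaussian
    white-noise drive, detects sequences with a torus-aware density-based
    clustering of thresholded pseudo-spikes, locates semi-transmissive
    "switch" regions with a max-tree merge analysis of the sequence-count
    landscape, and quantifies the effect of local synaptic modulation
    (patches) through transmission-probability motifs (Start, Repeat/Stop,
    Select, Gate) up to a context-reversal task circuit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
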