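Package: axonmapr
Title: Brain-Wide Quantification of Cell Class-Specific Axonal Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify brain-wide axonal projections of genetically
    defined cortical neuron classes from light-sheet imaging volumes.
    Starting from probabilistic axon segmentations, the package builds
    multi-threshold weighted skeletons, filters artifact components, maps
    axon coordinates into a 25 micrometre reference atlas with exact count
    conservation, normalizes density per labeled neuron, tabulates
    projections per brain region and hemisphere, computes categorical and
    spatial correlation matrices across injections, measures motor-cortex
    innervation hotspots and their mediolateral-to-anteroposterior
    topography, and analyzes wide-field calcium imaging responses to
    optogenetic stimulation (dF/F, evoked maps, masked centers of mass and
    the stimulation-site regression). A synthetic-data module generates
    toy atlases, tubular axon phantoms, injection cohorts with known
    mirror-map topography and wide-field sessions with full ground truth
    for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
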