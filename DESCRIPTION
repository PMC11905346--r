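Package: perturbmap
Title: Influence Mapping of Single-Neuron Photostimulation in Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon single-neuron photostimulation
    experiments with simultaneous population calcium imaging. Converts raw
    fluorescence to neuropil-corrected dF/F and deconvolved events, computes
    each stimulated neuron's trial-normalized influence on every other imaged
    neuron with a trial-shuffle significance null, aggregates influence into
    target-centered spatial maps and distance profiles with a
    difference-of-Gaussians center/surround fit, builds per-target population
    stimulus axes, and relates influence to locomotion state, pairwise noise
    correlations, and sound-frequency tuning. Includes a seeded synthetic
    session generator with known ground-truth influence kernels so the whole
    pipeline is testable end to end, plus permutation-test statistical
    machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
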