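Package: siftvoc
Title: Simulation and Interpretation of SIFT-MS Headspace Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for selected ion flow tube mass spectrometry (SIFT-MS)
    headspace analysis of volatile organic compounds, centred on the
    detection of chlorinated disinfection by-products. Provides
    unit-resolution ion mass arithmetic, binomial chlorine isotopologue
    envelopes and water-cluster (hydrate) ion series; a compound kinetics
    library mapping reagent ions to product-ion channels; a forward kinetic
    simulator that turns headspace compositions into Poisson-noisy spectra;
    pattern-based compound identification (delta-2 m/z chlorine multiplets,
    18 m/z hydrate ladders, ambiguity-preserving assignment); kinetics-based
    quantification with limit-of-detection handling; and an end-to-end
    study pipeline that aggregates replicates and compares aerobic versus
    anaerobic incubation with a stratified permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
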