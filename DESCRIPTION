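Package: fluxalign
Title: Comparison and Alignment of Central Carbon Metabolic Flux Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing quantitative metabolic flux distributions
    estimated by 13C metabolic flux analysis. Provides a validated flux-map
    data model with a documented TSV dialect and Excel ingest, substrate-uptake
    normalization, and four similarity measures between flux maps: angular
    cosine of the shared flux vectors, a Frobenius cosine of stoichiometry-
    weighted flux matrices, an enzyme-topology score, and a full topology-based
    alignment of weighted directed reaction graphs formulated as an integer
    program and solved exactly by branch and bound. Node similarity uses the
    EC-number hierarchy. Alignments come with Monte Carlo permutation P-values,
    a matched/conserved/gap/insertion report, and GraphML/SIF export. Also
    recalculates minimum and maximum ATP and NADPH production rates under
    cofactor-specificity wobbling, and generates mass-balanced synthetic flux
    maps for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    clue,
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
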