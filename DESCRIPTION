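Package: endoconn
Title: Whole-Brain Functional Connectivity Endophenotype Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and group analysis of weighted functional
    connectivity networks for endophenotype studies of autism spectrum
    conditions.  Provides a seeded synthetic-cohort generator (three matched
    groups with a graded global-connectivity gradient, band-limited signals,
    nuisance confounds and optional distance-dependent motion artifact),
    confound regression and spectral band-pass preprocessing, Pearson
    correlation networks with proportional thresholding, weighted graph
    metrics (strength, Onnela clustering, global efficiency) normalised
    against degree- and strength-preserving null ensembles, the node
    disruption index, hub topography over functional networks, framewise
    displacement motion diagnostics with permutation nulls, and three-group
    endophenotype statistics including one-way ANOVA reconstructed from
    printed summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
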