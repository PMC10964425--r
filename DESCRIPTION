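Package: gutweb
Title: Multi-Kingdom Gut Microbiome Co-Occurrence Networks, Contaminant
    Screening, and Indicator Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multi-kingdom (16S + ITS) amplicon
    count tables from host-associated microbiomes: reagent-contaminant
    screening driven by the inverse frequency/DNA-concentration signature
    with a no-template-control threshold-sweep selection rule; rarefaction
    and prevalence/abundance filtering; sparse signed co-occurrence network
    inference by centered log-ratio transform, lasso neighborhood selection
    and StARS stability selection; module detection, within-/among-module
    connectivity and keystone role classification; indicator power
    statistics linking fungal targets to bacterial assemblages; and
    distance-based community statistics (Bray-Curtis, PCoA, multivariate
    dispersion, PERMANOVA with interactions, patristic distances). Includes
    a synthetic-data generator with known ground truth (planted interaction
    graphs, contaminants, and host/geography effects) so every stage has a
    recoverable target at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    igraph,
    vegan,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
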