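Package: islescreen
Title: Island Site Screening for Genetically Engineered Mosquito Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for evaluating African islands as candidate
    field-trial sites for genetically engineered mosquitoes with gene drive.
    Implements island geographic-isolation indices (distance to mainland,
    UNEP Isolation Index, surrounding landmass proportion), elevation and
    steepest-gradient topography summaries, population-genetic statistics on
    diploid SNP data (Hudson's FST estimator, windowed nucleotide diversity,
    SNP filtering, LD pruning and PCA), anopheline species-richness and
    vector-status accounting, anthropogenic-dispersal summaries, and a
    threshold-based multi-criteria screening engine that aggregates
    per-criterion verdicts into candidate-site decisions. A synthetic-data
    module generates divergent-population genotypes under the
    Balding-Nichols model and land/water scenes with known geometry so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    vcfR,
    stringi,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
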