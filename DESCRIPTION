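Package: pneumotyper
Title: Pneumotype Analysis of Longitudinal Infant Airway Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community state typing ("pneumotypes") and longitudinal analysis of
    16S rRNA OTU tables from infant hypopharyngeal aspirates. Provides OTU-table
    quality control (read-depth and diversity-outlier exclusion), rarefaction,
    alpha diversity, weighted UniFrac and Jensen-Shannon beta diversity,
    partitioning-around-medoids clustering with silhouette-based model selection
    and permutation validation, group-equalised indicator-OTU (IndVal.g) analysis,
    per-subject core-microbiota statistics, pneumotype transition and stability
    tests, within- versus between-subject distance-ratio permutation tests, and a
    Dirichlet-multinomial generator of synthetic longitudinal cohorts with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    ape,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    phyloseq,
    optparse
Config/testthat/edition: 3
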