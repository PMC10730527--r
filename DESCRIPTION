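Package: modcompare
Title: Ontology-Integrated Protein Network Modules and Cross-Species
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds quality-enhanced protein-protein interaction networks by
    integrating interaction confidence scores with anatomy-ontology semantic
    similarity (information content based Lin and Schlicker measures), expands
    anatomical-entity protein modules by guilt-by-association candidate
    prediction (chi-square neighbourhood scoring with leave-one-out
    cross-validation and precision-threshold candidate calling), and compares
    homologous modules across two species through an ortholog map: conserved
    versus module-specific partitions, normalized weighted degree, Wilcoxon
    rank-sum tests, and Fisher-exact ontology enrichment. Includes a seeded
    synthetic-world generator (ontology, annotations, planted hub-biased
    modules, one-to-many orthology) so the whole workflow is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
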