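Package: microseed
Title: Community Assembly Processes and Co-Occurrence Networks for
    Marine Microbial OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diversity, null-model and network analysis of microbial
    operational taxonomic unit (OTU) tables from seasonal free-living and
    particle-associated seawater communities. Provides rarefaction and
    alpha diversity (Shannon, Chao1, Good's coverage), Bray-Curtis beta
    diversity with ANOSIM, the Stegen-style null-model partition of
    community assembly processes (beta mean nearest taxon distance,
    beta nearest taxon index, Bray-Curtis-based Raup-Crick metric, and
    the five-process classifier), Spearman co-occurrence network
    inference with Benjamini-Hochberg control, network topology and
    keystone-taxon detection, Mantel tests against environmental
    gradients, and a seeded synthetic-data generator with known assembly
    regimes and planted correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
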