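Package: ecoassembly
Title: Community Assembly Processes in Microbial Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Null-model partitioning of microbial community assembly processes
    (beta nearest taxon index, Bray-Curtis Raup-Crick, selection/dispersal
    ratios), Sloan neutral-model fitting with a binomial comparison, Levins
    niche breadth and community dispersal metrics, PCNM-based variation
    partitioning with forward selection, threshold indicator taxa analysis,
    and co-occurrence network inference with permutation/bootstrap edge
    significance, Brown's p-value combination and random-matrix-theory
    thresholding. Includes a synthetic metacommunity generator with known
    assembly regimes (neutral drift with migration, environmental selection,
    dispersal limitation) for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    vegan,
    igraph,
    geosphere,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
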