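Package: cophylospace
Title: Spatially Explicit Phylogenetic Congruence for Symbiont Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies phylogenetic congruence between two associated
    lineages (for example the fungal and algal partners of lichen
    symbioses) from paired genetic distance matrices and specimen
    locations. Implements uncorrected p and Tamura-Nei (TN93) pairwise
    distances from aligned sequences, principal coordinates analysis,
    Moran's eigenvector maps built from truncated geographic distances,
    distance-based redundancy analysis with permutation tests and forward
    selection of spatial eigenvectors, adjusted R-squared variance
    partitioning of genetic variation into partner, shared, purely
    spatial and unexplained fractions, and a Procrustes congruence test
    with association randomisation and per-specimen residual
    diagnostics. A co-phylogeny simulator with tunable co-speciation
    probability, host switching and spatial signal provides ground-truth
    data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
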