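Package: phyloscape
Title: Spatial Phylogenetic Diversity, Endemism and Turnover from
    Presence-Background Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline from species occurrence points to maps of taxonomic
    and phylogenetic diversity, endemism, null-model significance and
    compositional turnover. Per-species presence-background distribution
    models (penalized exponential models with linear, quadratic and hinge
    features, bias-layer background sampling and geographically structured
    evaluation) are thresholded at maximum sensitivity plus specificity,
    max-aggregated to a coarse grid and assembled into a presence-absence
    matrix, from which per-cell taxonomic diversity, weighted endemism,
    Faith phylogenetic diversity, Rosauer phylogenetic endemism and their
    relative (equal-branch-tree) counterparts are computed together with
    margin-preserving curveball null percentiles, pairwise Simpson and
    PhyloSor turnover, UPGMA bioregions and PCoA colour composition maps.
    A synthetic-data module generates landscapes, phylogenies, niches and
    spatially biased occurrence samples with known ground truth so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
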