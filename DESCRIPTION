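Package: assemblyscope
Title: Community Assembly Analysis for Amplicon Surveys Along Environmental Gradients
Version: 0.1.0
Authors@R: person("assemblyscope", "developers", role = c("aut", "cre"),
    email = "assemblyscope@example.org")
Description: Tools to quantify the ecological processes that structure
    microbial communities sampled along an environmental gradient. Provides
    alpha and beta diversity (Bray-Curtis, weighted UniFrac, PCoA,
    PERMANOVA, distance-decay), prevalence-thresholded Spearman
    co-occurrence networks with topology statistics, phylogenetic null
    models (SES.MNTD, beta-MNTD / beta-NTI), the Bray-Curtis based
    Raup-Crick null, the five-way partition of assembly processes into
    variable selection, homogeneous selection, dispersal limitation,
    homogenizing dispersal and drift, and fitting of the Sloan neutral
    community model. A synthetic-data module simulates communities under
    known assembly regimes (neutral dispersal-drift, homogeneous or
    variable selection, dispersal limitation) over a simulated phylogeny so
    that every analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    biomformat,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    withr
Suggests:
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
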