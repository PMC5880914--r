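Package: elevassembly
Title: Community Assembly Inference Along Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the statistical inference
    chain used to study soil bacterial community assembly along mountain
    elevational gradients: alpha-diversity (richness, Faith's phylogenetic
    diversity) and rarefaction, Jaccard and Bray-Curtis dissimilarities with
    distance-decay regressions, unconstrained and constrained ordination
    (PCoA, non-metric multidimensional scaling, canonical correspondence
    analysis, distance-based redundancy analysis), permutation tests
    (PERMANOVA, ANOSIM, MRPP, Mantel and partial Mantel, PERMDISP,
    Kruskal-Wallis with rank-based multiple comparisons), a richness-
    conserving occupancy-weighted null model with beta-deviation z-scores,
    PCNM spatial eigenvectors with forward selection and four-fraction
    variation partitioning plus a bootstrap fraction test, and partial least
    squares path modeling. A synthetic elevational-gradient community
    generator with known ground truth makes the whole chain testable without
    external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    biomformat,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
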