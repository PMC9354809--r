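Package: enterotyper
Title: Enterotype Clustering and Longitudinal Gut Microbiota Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stratifies microbial communities into enterotypes by partitioning
    around medoids on the square-root Jensen-Shannon divergence between
    genus-level relative-abundance profiles, with the number of clusters
    selected by the Calinski-Harabasz index and cross-validated by silhouette
    width and prediction strength. Provides the surrounding analysis pipeline
    for cohort studies: count-table preprocessing (rare-taxon filtering,
    rarefaction, genus aggregation, low-biomass flagging), alpha and beta
    diversity (Chao1, Shannon, Bray-Curtis, unweighted UniFrac), principal
    coordinates ordination with fitted driver-genus vectors, permutation
    inference (PERMANOVA, Mantel), univariate clinical-association screens,
    a compositional (centered log-ratio) differential-abundance test with
    two-method concordance filtering, and a Dirichlet-multinomial cohort
    simulator for end-to-end validation without access to cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    cluster,
    graphics,
    jsonlite,
    picante,
    stats,
    tools,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
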