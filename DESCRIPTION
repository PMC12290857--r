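Package: alenet
Title: Coordinate-Based Meta-Analysis and Brain-Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline from activation-coordinate tables to brain-network
    communities and receptor-density associations. Implements activation
    likelihood estimation (ALE) meta-analysis with an analytic null
    distribution and Monte-Carlo cluster-level family-wise error correction,
    permutation-based meta-analytic contrasts and conjunctions, network-node
    (peak) extraction, node-based resting-state functional connectivity with
    nuisance denoising, consensus Louvain community detection with
    participation coefficient and within-module degree z-score, connectivity
    gradient decomposition, and a distance-constrained random-network null
    model for annotation-map (e.g., PET receptor density) correlations.
    Includes synthetic-data generators that plant known spatial convergence,
    community structure, and metric-map couplings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    jsonlite
Config/testthat/edition: 3
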