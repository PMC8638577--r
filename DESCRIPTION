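Package: limbscale
Title: Whole-Limb Muscle Allometry and Phylogenetic Scaling in Amniotes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the scaling of whole-limb skeletal muscle
    mass, force-generating capacity and internal architecture across
    species. Computes per-muscle physiological cross-sectional area (PCSA),
    body-weight-normalized isometric strength and characteristic fascicle
    length, aggregates them over whole limbs or proximal/distal
    compartments, and fits log10-linear allometries by phylogenetic
    generalized least squares with maximum-likelihood estimation of
    Pagel's lambda. Includes phylogenetic and ordinary analysis of
    covariance for group comparisons of slopes and intercepts, pooled
    ("pan-amniote") predictive equations with confidence and prediction
    intervals and mean percent prediction error, and a fully seeded
    synthetic-data generator (trees, group-structured traits, per-muscle
    tables) for testing every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
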