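Package: navrsa
Title: Representational Similarity Analysis for Cue-Dissociation Spatial
    Navigation fMRI Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how spatial locations are encoded in
    multi-voxel fMRI activation patterns when navigation relies on a single
    cue type (a distal landmark or optic-flow self-motion).  The package
    generates second-order counterbalanced (de Bruijn) event schedules and
    session orderings, simulates behavioural responses and trial-wise
    voxel patterns from a three-subpopulation neuronal architecture (two
    cue-specific adapting populations driven by the true location and one
    shared non-adapting population driven by the reported location),
    computes cross-validated spatial information scores for location- and
    response-defined labels, decomposes pattern similarity into unique
    contributions of competing trial predictors, reconstructs the latent
    neural space of locations by multidimensional scaling with Procrustes
    alignment and permutation inference, links voxel-wise fMRI-adaptation
    effects to pattern-similarity effects via ranked voxel partitions with
    empirical chance levels, and provides the shared group-level
    statistics (directional t tests, JZS Bayes factors, repeated-measures
    trend contrasts, permutation Max-T familywise correction).
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
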