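Package: predgeom
Title: Predictive Learning and the Representational Geometry of Tone Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how statistical learning of auditory tone
    sequences reshapes neural representational geometry. Generates
    regularity-controlled triplet tone sequences, runs an entropy-weighted
    ideal-observer model of prediction error, computes cross-validated
    Mahalanobis (crossnobis) representational dissimilarity matrices across
    learning blocks, estimates Gaussian-copula mutual information between
    source-parcel signals and prediction-error trajectories, decomposes joint
    information into redundant and synergistic network components, and
    provides cluster-based permutation and network-based statistics. Includes
    a synthetic source-level data generator so the full pipeline is testable
    end to end without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
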