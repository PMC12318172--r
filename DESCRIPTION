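Package: isrsa
Title: Intersubject Representational Similarity Analysis with Trait-Based
    Dissimilarity Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intersubject representational similarity analysis
    (IS-RSA) of multi-voxel neuroimaging patterns, relating a
    participant-by-participant neural dissimilarity matrix to behavioral
    dissimilarity models built from a trait score: the nearest-neighbor
    model (normalized absolute score difference) and the Anna Karenina
    model (one minus the pair's normalized mean trait rank or mean score),
    tested with a seed-controlled Mantel permutation test (exhaustive for
    small samples) and Bonferroni correction across regions of interest.
    Also provides nonmetric multidimensional scaling by SMACOF with
    ordinal (isotonic) scaling, Gaussian kernel-density localization of
    the densest region of the embedding, individual-differences scaling
    (INDSCAL) of condition-level representational dissimilarity matrices
    with non-negative subject weights, split-half and cross-run pattern
    reliability, and a synthetic multi-subject data generator with
    planted Anna Karenina structure and a planted two-dimensional
    weighted-Euclidean geometry for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
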