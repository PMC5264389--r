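Package: odorhab
Title: Olfactory Habituation Analysis from Continuous Odor Intensity Ratings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify olfactory habituation from continuous odor
    intensity ratings and to relate it to physicochemical and sensory
    properties of odorants. Provides a synthetic-cohort generator with known
    generative truth, the exclusion and normalization rules for continuous
    rating curves, k-means clustering of habituation profiles with
    silhouette-guided model choice, a city-block habituation space,
    subject-random-effect mixed models with FDR-corrected pairwise
    comparisons, and a multi-response kernel PLS regression with
    leave-one-out RMSEP component selection and VIP-based ranking of
    habituation determinants.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    data.table,
    emmeans,
    jsonlite,
    nlme,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
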