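Package: fcsubtype
Title: Functional Connectivity Subtyping and Multivariate Brain-Behavior
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Defines resting-state functional connectivity (FC) subtypes by
    k-means clustering with the cosine distance, selects the number of
    clusters with an elbow criterion whose reliability is assessed by
    repeated half-sample resampling, and relates FC to group membership and
    behavior with partial least squares correlation (mean-centering and
    behavior PLS): singular value decomposition of the brain-design
    covariance, permutation tests on singular values, bootstrap-ratio
    stability of saliences, contrast expressions, and a permutation test for
    the contribution of resting-state network pairs to thresholded spatial
    patterns. Includes Fisher-z FC construction with age and acquisition-site
    (Helmert basis) confound regression, participant exclusion and
    Table-1-style group statistics, and a synthetic multi-site cohort
    generator with planted subtype, diagnosis, site, age and brain-behavior
    structure for end-to-end validation.
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
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
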