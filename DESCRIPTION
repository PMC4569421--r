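Package: strfkit
Title: Sparse Spectro-Temporal Receptive Field Estimation for Auditory
    Cortex Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates spectro-temporal receptive fields (STRFs) from
    neural responses to random gammatone chord stimuli using penalized
    Poisson and log-Gaussian generalized linear models with independent
    (L1) and grouped (L1/L2) sparsity, solved by proximal gradient
    (ISTA/FISTA). Includes an ERB-scaled gammatone stimulus generator,
    a forward encoding simulator with spike-history feedback,
    permutation-based selection of the regularization weight, nested-model
    deviance and F tests for the spike-history contribution, high-gamma
    band power extraction from field-potential traces, and extraction of
    best frequency, octave bandwidth and latency from fitted STRFs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
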