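Package: lwibench
Title: Benchmarking Missing-Data Handling for Lifelogs-Based Wellness Index Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation benchmark of six missing-data handling methods
    (listwise deletion, mean imputation, k-nearest-neighbor imputation,
    soft-thresholded SVD low-rank matrix completion, EM-based multiple
    imputation and predictive-mean-matching multiple imputation) for
    estimating the coefficients of a linear lifelogs-based wellness index
    from panel health-behavior data.  Includes a synthetic panel generator
    with Gaussian-copula low-rank structure and known ground-truth
    coefficients, an MCAR cell-deletion simulator over a 1-80% missingness
    grid, a Swamy-Arora feasible-GLS one-way random-effects fitter, Rubin's
    rules pooling, mean/grand-mean absolute-bias metrics, and
    Dunnett-modified Tukey-Kramer pairwise win counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
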