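Package: gclasso
Title: Conditional Granger-Causality Networks for Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed microbial interaction networks from genus-level
    abundance time series by conditional Granger causality: each genus is
    modelled as a lagged linear function of every genus in the community
    (a 20-lag vector autoregression), fitted equation-by-equation with
    LASSO penalization and rolling-origin cross-validated penalty
    selection. Includes the preprocessing chain for compositional,
    zero-inflated daily abundance tables (prevalence filtering, detection-
    threshold imputation, closure, standardization, first differencing),
    strong-edge extraction by signed top-percentile cuts, permutation
    (reshuffling) null validation, Pearson-correlation-versus-causality
    contingency analysis, cross-body-site conservation summaries, and a
    synthetic community generator with known ground-truth edges for
    parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    biomformat,
    jsonlite,
    withr
Config/testthat/edition: 3
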