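Package: patenttrends
Title: Patent-Filing Trend Analysis for Wildlife Trade Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting early-warning signals of commercial wildlife
    trade from patent-filing records. Provides keyword-based record filtering
    with include/exclude term semantics, monthly aggregation of filings,
    Bayesian single-changepoint inference for negative-binomial count series
    (exact quadrature oracle and a marginalized MCMC sampler with convergence
    diagnostics), latent Dirichlet allocation topic modelling of patent
    abstracts by collapsed Gibbs sampling with coherence/exclusivity model
    selection, iterative keyword-codebook thematic labeling, year-on-year
    trend statistics, a synthetic corpus generator with planted ground truth,
    and a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
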