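Package: mtpsens
Title: Dirichlet Process Sensitivity Analysis for Multiple Testing
    Procedures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Sensitivity analysis for multiple testing procedures (MTPs)
    based on marginal p-values under arbitrary dependence.  Places a
    Dirichlet process prior on the probability measure that generates
    the shape function of FDR-controlling step-up procedures, yielding a
    prior predictive distribution over the number of discoveries and a
    per-hypothesis probability of significance.  Also provides the
    classical Bonferroni, weighted Bonferroni, Holm, Sidak,
    Benjamini-Hochberg and Benjamini-Yekutieli procedures, a Gibbs
    sampler for the Dirichlet process precision parameter, a generator
    of dependent p-value families with known truth, and Monte-Carlo
    estimation of family-wise error and false discovery rates.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
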