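Package: pwidnet
Title: Combined Regression and Correlation-Network Analysis of Needle-Sharing Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing categorical risk-factor surveys of people who
    inject drugs (PWID) with a combination of logistic regression and
    correlation-network analysis. Provides univariate odds-ratio screening with
    Woolf confidence intervals and likelihood-ratio candidate selection,
    multivariate logistic modelling, Spearman correlation networks over ordinal
    factor codes with global topology statistics, an Erdos-Renyi null-model
    ensemble comparison, betweenness/closeness centrality ranking with
    above-average flagging, an implementation of the MCODE module-detection
    algorithm, and the intersection rule that nominates key harm-reduction
    target factors. A Gaussian-copula synthetic-survey generator calibrated to
    published marginal tables makes the full pipeline testable without access
    to subject-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
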