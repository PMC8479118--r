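Package: pseudobulkDE
Title: Evaluating Differential Expression Methods for Single-Cell
    Transcriptomics with Pseudobulk Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for evaluating differential expression (DE) methods
    in single-cell RNA-seq data. Implements single-cell DE tests (Wilcoxon
    rank-sum, Welch t, logistic regression, Poisson and negative binomial
    generalized linear models, bimodal and hurdle likelihood-ratio tests) and
    pseudobulk DE tests (negative binomial likelihood-ratio, quasi-likelihood
    F, and Wald tests with empirical-Bayes dispersion shrinkage; moderated t
    with a mean-variance trend; precision-weighted linear models), the area
    under the concordance curve (AUCC) between DE gene rankings,
    expression-bias diagnostics against spike-in panels, delta-variance
    analysis of pseudo-replicates, and a gamma-Poisson count simulator with
    controllable between-replicate heterogeneity for null experiments showing
    how DE methods that ignore biological replication produce false
    discoveries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
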