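Package: signda
Title: Sign- and Rank-Based Differential Abundance Testing for Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Differential abundance (DA) testing for taxon-by-sample count
    tables using sign and rank transformations relative to a reference frame
    of approximately invariant taxa. Counts are transformed to S-signs
    (taxon count below/tied-with/above an adjusted per-sample reference) or
    R-signs (pairwise between-sample comparisons of reference-scaled
    abundances), which are scale invariant, subcompositionally coherent and
    permutation invariant, and require no pseudocounts. Six testing
    procedures are provided: marginal and conditional logistic regression on
    S-signs (with Firth bias-reduced fallback under separation), marginal and
    conditional probabilistic index models on R-signs with a U-statistic
    sandwich variance, and regression-imputation (standardized) estimators of
    the marginal odds ratio and marginal probabilistic index with
    influence-curve variances. A negative-binomial simulation harness
    evaluates sensitivity, false discovery rate and type-I error under
    configurable fold changes and fractions of differentially abundant taxa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    jsonlite,
    knitr
Config/testthat/edition: 3
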