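Package: ptrsnet
Title: Co-Expression Modules and Polytranscript Risk Scores for
    Dimensional Child Psychopathology from Blood Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a blood
    transcriptome analysis of dimensional child psychopathology: weighted
    gene co-expression modules and their eigengenes, negative-binomial
    regression of Child Behavior Checklist (CBCL) syndrome t-scores on
    eigengenes with covariate and surrogate-variable adjustment,
    leukocyte deconvolution by iterative least squares against a
    signature matrix, permutation-calibrated surrogate variable analysis,
    hypergeometric gene-set over-representation, and polytranscript risk
    scoring with stratified cross-validation.  A synthetic cohort
    generator with planted ground truth (latent co-expression modules,
    NB2 counts, Dirichlet cell mixtures, a hidden batch factor, floored
    t-scores) makes every stage verifiable without access to controlled
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    limma,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mclust,
    sva,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
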