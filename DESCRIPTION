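Package: combiscreen
Title: Two-Stage Machine-Learning Screening and Permutation-Calibrated
    Testing for Genome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the COMBI approach to case-control genome-wide
    association analysis: a linear support vector machine is trained on
    one-hot encoded genotypes, its weight vector is collapsed per SNP and
    smoothed with a p-th order moving-average filter to respect linkage
    disequilibrium, and only the top-k SNPs per chromosome enter single-SNP
    association testing (Cochran-Armitage trend or 2-df chi-square).
    Significance thresholds are calibrated by Westfall-Young style
    permutation of the entire workflow, controlling the family-wise error
    rate, the generalized FWER, or the expected number of false rejections.
    Baselines (raw p-value thresholding with Bonferroni, fixed, or MinP
    thresholds; sample-splitting screening) and an LD-block-structured
    synthetic GWAS generator with known causal truth are included, together
    with evaluation utilities (confusion counts, ROC/PR curves, method
    comparison by Fisher's exact test, stability analysis) and Manhattan
    plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    ggplot2,
    vcfR,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
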