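Package: bloodFE
Title: Hematology and Whole-Blood Transcriptome Associations with Feed
    Efficiency Traits
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of continuous feed-efficiency traits
    (average daily gain, average daily feed intake, gain-to-feed) against
    complete-blood-count hematology profiles and whole-blood RNA-seq gene
    expression in growing beef heifers. Provides growth-curve derivation of
    average daily gain from serial body weights, a single-random-effect
    REML linear mixed model engine with design-rank checking, a
    per-parameter hematology association scan with baseline R-squared
    accounting, count-matrix preprocessing (low-expression filtering,
    median-of-ratios normalization, PCA with a confidence-ellipse sample
    outlier screen), and a continuous-trait differential-expression
    procedure that residualizes both expression and trait on herd design
    factors and blood cell-type proportions before gene-wise Pearson
    correlation with Benjamini-Hochberg false discovery rate control.
    Includes a fully parameterized synthetic-herd generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    lme4,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
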