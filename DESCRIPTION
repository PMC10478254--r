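Package: stressStrat
Title: Stratification of Brain Transcriptomes by Stress-Responsive Gene
    Expression with TUNEL Histology Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stratifies bulk RNA-seq cohorts into high and low
    stress-response subgroups from a panel of stress-responsive genes
    (Z-score standardization, Ward agglomerative clustering with an
    SPSS-style rescaled-distance cut, and directional concordance
    labeling), computes a quartile-weighted stress-response index for
    control subjects, ranks differentially expressed genes and tests
    gene-set overrepresentation by the hypergeometric distribution, and
    quantifies TUNEL positivity in brightfield histology images by
    optical-density color deconvolution, isodata thresholding and
    particle analysis. Includes a synthetic-data generator (negative
    binomial cohorts with planted subgroup effects and a planted gene
    set; rendered two-stain histology fields with known ground truth)
    so that every stage is testable without access to protected
    postmortem data, and exact nonparametric tests (Mann-Whitney U,
    Fisher 2x2 and RxC) validated against brute-force enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite,
    png,
    S4Vectors,
    SummarizedExperiment,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
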