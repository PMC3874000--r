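Package: qihc
Title: Unbiased Quantitative Immunohistochemistry and Colocalization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies DAB chromogen signal in brightfield images of tissue
    microarray cores by threshold-and-particle analysis, standardizes the
    signal to the amount of tissue per core via inverse-image segmentation,
    and carries the per-core measurements through cohort-level statistics
    (Mann-Whitney U, Kolmogorov-Smirnov normality, fold change, mountain-plot
    AUC), biomarker operating characteristics (probit transform, empirical and
    binormal ROC, likelihood ratios, two-marker logistic regression) and
    pixel-wise Pearson colocalization of fluorescence channel pairs for
    relapse stratification. A synthetic tissue-core generator with known
    ground-truth masks, target channel correlations and prescribed cohort
    moments lets every stage run and be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
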