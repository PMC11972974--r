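Package: oaprs
Title: Overlap-Adjusted Polygenic Risk Scores from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes the contribution of known overlapping samples from
    consortium GWAS summary statistics by inverting fixed-effect
    meta-analysis (inverse-variance weighted and sample-size weighted
    Z-score methods), with a de-correlation comparator, so that polygenic
    risk scores built from the adjusted summaries are free of
    sample-overlap overfitting. Includes allele harmonization of summary
    tables, a clumping + P-value thresholding score constructor,
    AUROC/odds-ratio evaluation stratified by overlap status, a visual
    diagnostic that traces AUROC while progressively excluding associated
    variants, and a synthetic genotype/phenotype simulator with controlled
    overlap injection for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
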