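Package: promoterlearn
Title: Promoter Activity Prediction from DNA Sequence Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts quantitative promoter activity from DNA sequence alone,
    following the window-based strategy that won the DREAM6 gene-expression
    prediction challenge for yeast ribosomal-protein promoters. Promoters are
    segmented into non-overlapping windows anchored at the translation start
    site; per-window features (k-mer frequencies for k = 1..5, homopolymeric
    and alternating tract lengths, and mean DNA mechanical properties from
    di/trinucleotide parameter scales) feed a cross-validated linear-regression
    wrapper for feature selection and an averaged ensemble of epsilon-SVM
    regressors. The package also implements the challenge's four-statistic
    permutation-null evaluation scheme (Pearson, Spearman, chi-square distance,
    rank distance, combined scores) and a synthetic promoter generator with
    planted feature-activity structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
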