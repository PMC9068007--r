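Package: iiscore
Title: Immune Infiltration Scoring for Paired Tumour Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an immune infiltration score (IIS) from bulk expression of
    matched tumour and para-cancerous tissue. Cell-type content is estimated per
    sample with a rank-based single-sample enrichment statistic, up- and
    down-shifted cell types are identified by paired t-tests, contents are
    z-normalised against reference-cohort statistics and summed into two
    indicators, and a linear decision boundary (soft-margin SVM or logistic
    regression, with published coefficients built in) scores and stratifies
    samples at a cutoff of zero. Includes Kaplan-Meier, log-rank, rank-sum and
    chi-square comparisons between score strata, and a synthetic paired-cohort
    generator with planted effects for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
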