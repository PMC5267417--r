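Package: methblocks
Title: Candidate-Gene CpG Co-Methylation Block Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of candidate-gene CpG methylation measured on the
    Illumina 450k platform: beta/M-value transforms and region-level
    summaries, pairwise Pearson correlation structure and detection of
    co-methylation blocks under contiguity and pair-density criteria,
    cross-age stability of per-site methylation, region-level age-change
    testing with generalized estimating equations (identity link,
    exchangeable working correlation, sandwich variance), per-site sex
    difference tests, and sex-adjusted regressions of body-size outcomes
    on methylation. Includes a latent-factor synthetic cohort generator
    with planted correlation blocks, sex effects, cross-age stability and
    outcome effects, so every stage of the pipeline can be exercised and
    calibrated without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
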