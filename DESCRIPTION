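Package: rejuvclock
Title: Epigenetic Clocks, Rejuvenation Quantification, EWAS and IgG Glycan
    Aging Analysis for Methylation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and cross-validates penalized-regression epigenetic clocks
    from DNA methylation beta matrices, including pan-tissue, tissue-specific
    and dual-species relative-age clocks; quantifies treatment-induced
    epigenetic rejuvenation; runs a per-CpG epigenome-wide association
    analysis of age and treatment with unwanted-variation factors and
    empirical-Bayes variance moderation; and analyses IgG Fc N-glycan aging
    with rank-based inverse-normal transforms and mixed-effects models.
    Ships a synthetic-data generator with planted ground truth so the full
    pipeline can be exercised and scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    purrr,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
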