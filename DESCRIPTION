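Package: crossmetsig
Title: Cross-Species Metabolic Signature Scoring and Tumor Similarity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores bulk tumor expression profiles over conserved metabolic
    pathways with a single-sample gene-set enrichment (ssGSEA) running-sum
    statistic, classifies query tumor samples as metabolically similar or
    non-similar to a fly-tumor reference signature via a Pearson correlation
    test with multiple-testing adjustment, and runs the downstream cohort
    contrasts (mutation-event enrichment by Fisher's exact test, age,
    mutation load and DNA-methylation comparisons by Welch t-test, two-group
    log-rank survival). Also provides LC-MS metabolite concentration
    normalization with rank-sum genotype comparisons, and a seeded synthetic
    cohort generator so the whole pipeline is testable without external data.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
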