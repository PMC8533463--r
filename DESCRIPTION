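Package: cernet
Title: Shared Competing Endogenous RNA Network Discovery Across Tumor Cohorts
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers lncRNA- and pseudogene-mediated competing endogenous RNA
    (ceRNA) triplets that are shared across multiple tumor cohorts. Implements
    TMM normalisation, log-CPM transformation, low-expression filtering and
    empirical-Bayes moderated t differential expression; a three-step sponge
    screen combining a hypergeometric shared-miRNA test, a positive Pearson
    correlation filter and the multiple sensitivity correlation (mscor) with
    empirical null p-values; cross-cohort integration of triplets via canonical
    keys and a one-way frequency rule with Venn-style sharing counts; and
    downstream median-split Kaplan-Meier/logrank prognostic screens and GMT
    gene-set over-representation. A seeded synthetic-study generator with
    planted ground truth supports recovery- and calibration-based testing at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    limma,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
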