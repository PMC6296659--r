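Package: wescnv
Title: Copy-Number and Aneuploidy Detection from Exome Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls copy-number variants from whole-exome sequencing read
    depth using a beta-binomial emission model with hidden-Markov
    segmentation and Bayes-factor scoring, detects whole-chromosome
    aneuploidy and mosaicism from capture-restricted coverage ratios with
    the Grubbs outlier test, annotates and tiers calls against interval
    databases, and evaluates concordance with array-based gold-standard
    call sets. Includes a seeded synthetic cohort generator so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
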