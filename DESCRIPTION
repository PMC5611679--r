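Package: hrrnet
Title: Highest Reciprocal Rank Co-Expression Neighborhoods and GO Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extracts co-expression neighborhoods of query genes from TPM
    expression matrices using the Highest Reciprocal Rank (HRR) of Pearson
    correlations, compares the resulting gene lists within a species
    (exclusive Venn region counts) and across species through a possibly
    many-to-many ortholog map, and tests GO-term over-representation with an
    upper-tail hypergeometric test. Ships a planted-module synthetic
    expression generator with ground-truth labels so every stage of the
    pipeline can be validated without external data, plus an end-to-end
    reproducible pipeline runner and command-line interface.
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
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
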