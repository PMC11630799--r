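Package: radhab
Title: Radiolytic Dose Modelling and Microbial Survival in Subsurface Brines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the habitability of radiolytically enriched
    subsurface brines. Builds irradiation scenarios from radionuclide dose
    rates and particle mixes, computes biologically weighted accumulated
    doses and radiolytic species production from G-values, extrapolates
    published microbial survival curves to a one-in-a-million survival
    threshold via log-linear (D10) fitting, and derives time-to-inactivation
    tables for dormant single-species populations. Also implements the
    genome-annotation summaries used alongside such analyses: KEGG-style
    module completeness scoring, threshold presence calls, genus-level
    aggregation over the most complete genomes, taxonomy composition,
    quality-based genome retention and tiering filters, contig trim/length
    filtering, and ANI-based genus assignment, together with seeded
    synthetic-data generators so every stage is testable without sequence
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
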