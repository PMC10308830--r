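Package: chembiblio
Title: Bibliometric Analysis of Chemicals Measured in Environmental Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bibliometric surveys of chemical occurrence literature
    indexed by CAS Registry Number (CASRN). Provides CASRN check-digit
    validation and canonicalization, readers for citation corpora, chemical
    class lists and industrial chemical inventories, earliest-year
    deduplication of substance reports, declarative exclusion screening,
    precedence-ordered classification against suspect-screening and priority
    lists, temporal trend and top-N citation-concentration statistics
    (the "Matthew effect"), three-way inventory overlap analysis, and a
    seeded synthetic literature-corpus generator with exported ground truth
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
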