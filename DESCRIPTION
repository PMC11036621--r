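Package: genesyn
Title: Standardizing Mitochondrial and Chloroplast Gene Nomenclature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving the many names under which organelle genes are
    annotated. Builds a synonym database of mitochondrial and chloroplast
    gene-name variants by scanning GenBank flat-file genome records,
    standardizes any observed variant to a HUGO-style canonical short symbol
    (e.g. "cytochrome c oxidase subunit 1" to "COI"), and renders advanced
    Entrez-style search queries that OR-join every known synonym of a marker
    for GenBank and PubMedCentral searches. Includes a deterministic synthetic
    genome generator so the whole pipeline is testable offline, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
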