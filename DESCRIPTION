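Package: mihakit
Title: Reverse-Immunology Discovery and Combinatorial Multimer Monitoring
    of Minor Histocompatibility Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico discovery and flow-cytometric
    monitoring of HLA-A2-restricted minor histocompatibility antigens
    (MiHA) after allogeneic stem cell transplantation. Enumerates
    candidate allelic peptide pairs (9/10-mers) around nonsynonymous
    SNPs, predicts peptide-HLA dissociation half-times from
    position-coefficient tables, filters candidates by the
    Hardy-Weinberg donor-recipient disparity probability ("clinical
    applicability"), classifies peptide-exchange ELISA readings into
    affinity classes, designs combinatorial dual-fluorochrome multimer
    panels with pooled screening layouts, and decodes flow-cytometry
    event tables into per-specificity T cell frequencies. Seeded
    generators produce every input with known ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
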