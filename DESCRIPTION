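Package: aspcr
Title: Allele-Specific PCR Assay Design and In Silico Validation for DNA Barcoding
Version: 0.1.0
Authors@R:
    person("ASPCR", "Developers", email = "aspcr@example.org", role = c("aut", "cre"))
Description: Toolkit for sequence-based species authentication. Discovers
    species-diagnostic SNPs (strict fixed differences) in a species-labelled
    DNA-barcode alignment, designs allele-specific PCR primers that anchor the
    diagnostic allele at the 3' terminus and carry an engineered destabilizing
    mismatch at the antepenultimate position, verifies assay specificity with an
    in silico PCR binding model that encodes 3'-mismatch extension blocking, and
    confirms target-species monophyly with a from-scratch neighbor-joining /
    bootstrap engine over p, Jukes-Cantor and Kimura 2-parameter distances.
    Includes a seeded synthetic-alignment generator with planted diagnostic
    sites and a command-line interface chaining all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
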