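Package: auxotrophr
Title: Genome-Based Inference of Amino Acid Auxotrophy in Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers amino acid auxotrophies of bacterial genomes from
    protein-hit evidence against reference biosynthesis pathways.
    Implements pathway-completeness scoring with medium-confidence
    candidate rules, threshold-calibrated auxotrophy calling validated
    against experimentally known phenotypes, habitat-level mapping of
    auxotrophy prevalence via 16S rRNA ASV-to-genome matching, and
    genomic-correlate analyses (genome size, biosynthetic cost, COG
    category enrichment). A synthetic-data generator with planted ground
    truth makes every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
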