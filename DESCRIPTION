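Package: occseq
Title: Harvest Occurrence-Linked Small-Subunit rRNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links biodiversity occurrence records to the next-generation
    small-subunit (SSU) rRNA reads that support them. For a genus or
    binomial query, occseq pages through GBIF-style occurrence search
    results, resolves each occurrence's linked sequence resources
    (FASTA/FASTQ plus MAPseq taxonomy-assignment files), extracts exactly
    the reads classified as the query taxon, and writes a master FASTA
    linked row-for-row to an occurrence metadata table, together with a
    coverage summary. A deterministic fixture generator and an offline
    transport make every stage testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    tools,
    utils,
    stats,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
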