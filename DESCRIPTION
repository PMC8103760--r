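Package: dropsnv
Title: Consensus Molecule Collapsing and SNV Calling for Droplet Single-Cell RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment toolkit for droplet single-cell RNA-seq (10x-style
    3' chemistry). Collapses UMI duplicates into longer consensus molecules via
    directional UMI deduplication, calls single-nucleotide variants from
    strand- and barcode-aware pileups with explicit coverage, allele-fraction
    and read-end filters, annotates candidate A-to-I (A>G) RNA edits against an
    edit catalogue and Alu-like repeat intervals, identifies cell-containing
    barcodes with an elbow estimate plus MAD outlier filters, benchmarks calls
    against matched DNA evidence (pseudo-bulk and per cell), simulates
    homozygous SNVs by reference modification, and extracts per-molecule SNV
    co-expression sets. Includes a deterministic synthetic-data generator that
    emulates tagged 3'-biased molecules with cell barcodes, UMI and PCR
    duplicates, planted germline SNVs and clustered edits, so the whole
    pipeline can be validated against known truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    stats,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5,
    ShortRead,
    jsonlite,
    vcfR,
    optparse
Config/testthat/edition: 3
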