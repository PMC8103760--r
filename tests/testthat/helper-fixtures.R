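# Shared small fixtures, built in code at test time.

tiny_cfg <- function(...) {
  synth_config(n_genes = 20L, genes_per_contig = 20L, n_cells = 20L,
               ambient_barcodes = 10L, molecules_per_cell = 30,
               n_hom = 3L, n_het = 3L, n_edit_clusters = 1L, ...)
}

# small dataset cached per test session
.tiny_env <- new.env()
tiny_dataset <- function(seed = 7L) {
  key <- paste0("d", seed)
  if (is.null(.tiny_env[[key]])) {
    cfg <- tiny_cfg()
    ref <- generate_reference(cfg, seed = seed)
    v <- plant_variants(ref, cfg, seed = seed)
    lib <- generate_library(ref, v, cfg, seed = seed)
    paths <- write_reference(ref, file.path(tempdir(), paste0("tinyref", seed)))
    idx <- build_index(paths$gtf, paths$fasta)
    .tiny_env[[key]] <- list(cfg = cfg, ref = ref, variants = v, lib = lib,
                             paths = paths, index = idx)
  }
  .tiny_env[[key]]
}

# hand-written two-gene reference with exactly known coordinates:
#   chrT (600 bp):
#     GP (+): exons [100,200) and [300,400)  -> intron [200,300)
#     GM (-): exons [420,470) and [520,570)  -> intron [470,520)
toy_index <- function() {
  dir <- file.path(tempdir(), "toyref")
  dir.create(dir, showWarnings = FALSE)
  set.seed(42)
  genome_seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                      collapse = "")
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chrT", genome_seq), fa)
  gtf <- file.path(dir, "toy.gtf")
  attr1 <- 'gene_id "GP"; transcript_id "TP"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";'
  attr2 <- 'gene_id "GM"; transcript_id "TM"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";'
  writeLines(c(
    sprintf("chrT\ttoy\texon\t%d\t%d\t.\t+\t.\t%s", 101, 200, attr1),
    sprintf("chrT\ttoy\texon\t%d\t%d\t.\t+\t.\t%s", 301, 400, attr1),
    sprintf("chrT\ttoy\texon\t%d\t%d\t.\t-\t.\t%s", 421, 470, attr2),
    sprintf("chrT\ttoy\texon\t%d\t%d\t.\t-\t.\t%s", 521, 570, attr2)
  ), gtf)
  build_index(gtf, fa)
}

# minimal alignment-record table for pileup tests
mk_records <- function(contig, pos, cigar, strand, seq, qual, barcode,
                       internal_ends = NULL) {
  dt <- data.table::data.table(contig = contig, pos = pos, cigar = cigar,
                               strand = strand, seq = seq, qual = qual,
                               barcode = barcode)
  if (!is.null(internal_ends)) dt[, internal_ends := internal_ends]
  dt
}
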