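test_that("transcript filters drop excluded biotypes and short transcripts", {
  dir <- withr::local_tempdir()
  set.seed(11)
  writeLines(c(">c1", paste(sample(c("A", "C", "G", "T"), 9000, replace = TRUE),
                            collapse = "")), file.path(dir, "g.fa"))
  at <- function(g, t, b) {
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "protein_coding"; transcript_biotype "%s";',
            g, t, b)
  }
  writeLines(c(
    # 99 bp transcript: excluded by the length filter
    sprintf("c1\tx\texon\t%d\t%d\t.\t+\t.\t%s", 101, 199, at("g1", "t99", "protein_coding")),
    # 100 bp transcript: boundary, included
    sprintf("c1\tx\texon\t%d\t%d\t.\t+\t.\t%s", 1101, 1200, at("g2", "t100", "protein_coding")),
    # long retained_intron transcript: excluded by biotype
    sprintf("c1\tx\texon\t%d\t%d\t.\t+\t.\t%s", 2101, 7100, at("g3", "tri", "retained_intron")),
    # ordinary two-exon transcript
    sprintf("c1\tx\texon\t%d\t%d\t.\t+\t.\t%s", 7301, 7500, at("g4", "tok", "protein_coding")),
    sprintf("c1\tx\texon\t%d\t%d\t.\t+\t.\t%s", 7801, 8000, at("g4", "tok", "protein_coding"))
  ), file.path(dir, "g.gtf"))

  idx <- build_index(file.path(dir, "g.gtf"), file.path(dir, "g.fa"))
  expect_false("t99" %in% idx$transcripts$transcript_id)
  expect_true("t100" %in% idx$transcripts$transcript_id)
  expect_false("tri" %in% idx$transcripts$transcript_id)
  expect_true("tok" %in% idx$transcripts$transcript_id)
  # junctions only from retained transcripts
  expect_equal(nrow(idx$junctions), 1L)
  expect_equal(idx$junctions$donor, 7500L)
  expect_equal(idx$junctions$acceptor, 7800L)

  # shrinking the excluded set never removes a previously retained transcript
  idx2 <- build_index(file.path(dir, "g.gtf"), file.path(dir, "g.fa"),
                      excluded_biotypes = character(0))
  expect_true(all(idx$transcripts$transcript_id %in%
                    idx2$transcripts$transcript_id))

  # referencing an unknown contig is a hard error
  writeLines(sprintf("c9\tx\texon\t%d\t%d\t.\t+\t.\t%s", 1, 200,
                     at("g9", "t9", "protein_coding")),
             file.path(dir, "bad.gtf"))
  expect_error(build_index(file.path(dir, "bad.gtf"), file.path(dir, "g.fa")),
               "unknown contig")
  # exon beyond contig bounds is a hard error
  writeLines(sprintf("c1\tx\texon\t%d\t%d\t.\t+\t.\t%s", 8900, 9100,
                     at("g9", "t9", "protein_coding")),
             file.path(dir, "oob.gtf"))
  expect_error(build_index(file.path(dir, "oob.gtf"), file.path(dir, "g.fa")),
               "outside contig bounds")
})

test_that("transcript alignments project onto the genome across junctions", {
  idx <- toy_index()
  # fully inside the first exon of the plus-strand transcript
  p <- project_to_genome(idx, "TP", 10L, "50M")
  expect_equal(p$contig, "chrT")
  expect_equal(p$pos, 110L)
  expect_equal(p$cigar, "50M")
  expect_equal(p$strand, "+")
  # spanning the junction: intron of 100 bp becomes a 100N skip
  p <- project_to_genome(idx, "TP", 80L, "40M")
  expect_equal(p$pos, 180L)
  expect_equal(p$cigar, "20M100N20M")
  # minus-strand transcript: genomic strand flips, coordinates ascend
  p <- project_to_genome(idx, "TM", 0L, "60M")
  expect_equal(p$strand, "-")
  expect_equal(p$cigar, "10M50N50M")
  expect_equal(p$pos, 460L)
  # out-of-bounds alignments error
  expect_error(project_to_genome(idx, "TP", 190L, "50M"), "bounds")
  expect_error(project_to_genome(idx, "XX", 0L, "10M"), "exon chain")
})

test_that("projection agrees with a per-base exon-walk oracle", {
  d <- tiny_dataset()
  idx <- d$index
  set.seed(5)
  for (tid in sample(idx$transcripts$transcript_id, 8)) {
    len <- idx$transcripts$length[idx$transcripts$transcript_id == tid]
    s <- sample.int(len - 30L, 1L) - 1L
    w <- sample(10:min(120L, len - s), 1L)
    p <- project_to_genome(idx, tid, s, paste0(w, "M"))
    got <- oracle_aln_positions(p$pos, p$cigar)
    want <- sort(oracle_tx_map(idx, tid, seq(s, s + w - 1L)))
    expect_equal(got, want)
  }
})

test_that("per-gene exon/intron overlap is measured in aligned bases", {
  idx <- toy_index()
  # 98 bp fully inside the [100,200) exon of GP
  ov <- annotate_overlap(data.table::data.table(
    aln_id = 1L, contig = "chrT", pos = 101L, cigar = "98M", strand = "+"), idx)
  expect_equal(ov$gene_id, "GP")
  expect_equal(ov$exon_bp, 98L)
  expect_equal(ov$intron_bp, 0L)
  expect_false(ov$antisense)
  # block straddling the exon/intron boundary with 26 bp in the exon
  ov <- annotate_overlap(data.table::data.table(
    aln_id = 1L, contig = "chrT", pos = 174L, cigar = "98M", strand = "+"), idx)
  expect_equal(ov$exon_bp, 26L)
  expect_equal(ov$intron_bp, 72L)
  # intergenic block: empty result
  ov <- annotate_overlap(data.table::data.table(
    aln_id = 1L, contig = "chrT", pos = 0L, cigar = "50M", strand = "+"), idx)
  expect_equal(nrow(ov), 0L)
  # antisense flag against the minus-strand gene
  ov <- annotate_overlap(data.table::data.table(
    aln_id = 1L, contig = "chrT", pos = 425L, cigar = "30M", strand = "+"), idx)
  expect_true(ov$antisense)
})

test_that("overlap conservation: exon + intron + intergenic == aligned bases", {
  d <- tiny_dataset()
  idx <- d$index
  rd <- d$lib$reads[seq_len(200)]
  ov <- annotate_overlap(
    data.table::data.table(aln_id = seq_len(nrow(rd)), contig = rd$contig,
                           pos = rd$pos, cigar = rd$cigar, strand = rd$strand),
    idx)
  segs <- GenomicAlignments::cigarWidthAlongReferenceSpace(rd$cigar, N.regions.removed = TRUE)
  # per alignment, summed gene overlap cannot exceed aligned bases, and for
  # sense single-gene hits the exon+intron total must equal the aligned width
  tot <- ov[, .(bp = sum(exon_bp + intron_bp)), by = aln_id]
  expect_true(all(tot$bp <= segs[tot$aln_id] * 2))  # antisense pairs may double-count
  sense <- ov[antisense == FALSE]
  one <- sense[, .N, by = aln_id][N == 1L, aln_id]
  s1 <- sense[aln_id %in% one]
  expect_true(all(s1$exon_bp + s1$intron_bp <= segs[s1$aln_id]))
})

test_that("transcript sequences splice and orient correctly", {
  idx <- toy_index()
  g <- idx$genome[["chrT"]]
  sp <- transcript_seq(idx, "TP")
  expect_equal(nchar(sp), 200L)
  expect_equal(sp, paste0(as.character(Biostrings::subseq(g, 101, 200)),
                          as.character(Biostrings::subseq(g, 301, 400))))
  sm <- transcript_seq(idx, "TM")
  expect_equal(sm, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(
      as.character(Biostrings::subseq(g, 421, 470)),
      as.character(Biostrings::subseq(g, 521, 570)))))))
})
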