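test_that("score filtering keeps the within-window best alignments", {
  cand <- data.table::data.table(
    contig = "c1", pos = c(10L, 500L, 900L), cigar = "50M", strand = "+",
    score = c(50L, 48L, 46L))
  kept <- merge_and_filter(cand)
  expect_equal(sort(kept$score), c(48L, 50L))
  # a single candidate below the absolute cutoff leaves the read unmapped
  expect_equal(nrow(merge_and_filter(cand[1][, score := 44L])), 0L)
  # genic and intergenic candidates participate equally
  cand2 <- data.table::data.table(
    contig = "c1", pos = c(10L, 5000L), cigar = "50M", strand = "+",
    score = c(50L, 50L), gene = c("G", NA))
  expect_equal(nrow(merge_and_filter(cand2)), 2L)
  # duplicates by position collapse first
  cand3 <- rbind(cand[1], cand[1])
  expect_equal(nrow(merge_and_filter(cand3)), 1L)
})

test_that("splice overhangs of at most 5 bp are soft-clipped", {
  idx <- toy_index()  # junction: donor 200, acceptor 300 on chrT
  # terminal block crossing the donor by exactly 5 bp
  aln <- data.table::data.table(aln_id = 1L, contig = "chrT", pos = 150L,
                                cigar = "55M", strand = "+")
  tr <- trim_splice_overhang(aln, idx)
  expect_equal(tr$cigar, "50M5S")
  expect_equal(tr$pos, 150L)
  # 6 bp overhang: unchanged
  aln$cigar <- "56M"
  expect_equal(trim_splice_overhang(aln, idx)$cigar, "56M")
  # 5' end starting 4 bp before the acceptor
  aln2 <- data.table::data.table(aln_id = 1L, contig = "chrT", pos = 296L,
                                 cigar = "50M", strand = "+")
  tr2 <- trim_splice_overhang(aln2, idx)
  expect_equal(tr2$cigar, "4S46M")
  expect_equal(tr2$pos, 300L)
  # no junction in span: identity
  aln3 <- data.table::data.table(aln_id = 1L, contig = "chrT", pos = 110L,
                                 cigar = "40M", strand = "+")
  expect_equal(trim_splice_overhang(aln3, idx)$cigar, "40M")
  # trimming never increases aligned length
  w0 <- GenomicAlignments::cigarWidthAlongQuerySpace("55M", after.soft.clipping = TRUE)
  w1 <- GenomicAlignments::cigarWidthAlongQuerySpace(tr$cigar, after.soft.clipping = TRUE)
  expect_lte(w1, w0)
})

test_that("alignment types follow the overlap schema at its printed boundaries", {
  ov1 <- data.table::data.table(gene_id = "G", exon_bp = 26L, intron_bp = 0L,
                                antisense = FALSE)
  expect_equal(classify_alignment("genome", ov1)$type, "exonic")
  ov2 <- data.table::data.table(gene_id = "G", exon_bp = 25L, intron_bp = 0L,
                                antisense = FALSE)
  expect_false(classify_alignment("genome", ov2)$type == "exonic")
  ov3 <- data.table::data.table(gene_id = "G", exon_bp = 0L, intron_bp = 6L,
                                antisense = FALSE)
  expect_equal(classify_alignment("genome", ov3)$type, "intronic")
  ov4 <- data.table::data.table(gene_id = "G", exon_bp = 0L, intron_bp = 5L,
                                antisense = FALSE)
  expect_equal(classify_alignment("genome", ov4)$type, "intergenic")
  # any exon overlap blocks the intronic class
  ov5 <- data.table::data.table(gene_id = "G", exon_bp = 10L, intron_bp = 80L,
                                antisense = FALSE)
  expect_equal(classify_alignment("genome", ov5)$type, "intergenic")
  # transcriptome alignments are exonic by construction
  expect_equal(classify_alignment("transcriptome", ov4)$type, "exonic")
  # antisense-only overlap
  ov6 <- data.table::data.table(gene_id = "G", exon_bp = 50L, intron_bp = 0L,
                                antisense = TRUE)
  expect_equal(classify_alignment("genome", ov6)$type, "antisense")
  # two sense genes: ambiguous
  ov7 <- data.table::data.table(gene_id = c("G1", "G2"), exon_bp = c(30L, 30L),
                                intron_bp = 0L, antisense = FALSE)
  expect_equal(classify_alignment("genome", ov7)$type, "ambiguous")
})

test_that("read-level annotation resolves multi-mapping and mixed alignments", {
  one <- annotate_read("exonic", "G", "c1", 100L, 198L)
  expect_equal(one$annotation, "exonic")
  expect_equal(one$gene_id, "G")
  # equal-score exonic + distant intergenic: multi-mapped
  mm <- annotate_read(c("exonic", "intergenic"), c("G", NA),
                      c("c1", "c1"), c(100L, 90000L), c(198L, 90098L))
  expect_equal(mm$annotation, "multi_mapped")
  # intronic and exonic within the same gene: ambiguous
  amb <- annotate_read(c("exonic", "intronic"), c("G", "G"),
                       c("c1", "c1"), c(100L, 120L), c(198L, 218L))
  expect_equal(amb$annotation, "ambiguous")
  # all antisense
  as_ <- annotate_read(c("antisense", "antisense"), c(NA, NA),
                       c("c1", "c1"), c(100L, 105L), c(198L, 203L))
  expect_equal(as_$annotation, "antisense")
  # redundant projections (same location, >=50% reciprocal overlap) are one
  # location: not multi-mapped
  same <- annotate_read(c("exonic", "exonic"), c("G", "G"),
                        c("c1", "c1"), c(100L, 110L), c(198L, 208L))
  expect_equal(same$annotation, "exonic")
  # no alignments: unmapped
  expect_equal(annotate_read(character(0), character(0), character(0),
                             integer(0), integer(0))$annotation, "unmapped")
})

test_that("gold synthetic reads all classify to their true genes", {
  d <- tiny_dataset()
  ann <- annotate_reads(d$lib$reads[, .(read_id, contig, pos, cigar, strand,
                                        source)], d$index)
  cmp <- merge(ann, d$lib$reads[, .(read_id, true_gene = gene_id)],
               by = "read_id")
  expect_true(all(cmp$annotation %in% c("exonic", "intronic")))
  expect_equal(cmp$gene_id, cmp$true_gene)
  # spliced molecules give exonic reads, intronic molecules intronic reads
  mols <- d$lib$truth$molecules
  rd <- merge(d$lib$reads[, .(read_id, mol_id)], mols[, .(mol_id, intronic)],
              by = "mol_id")
  cmp2 <- merge(cmp, rd, by = "read_id")
  expect_equal(cmp2$annotation == "intronic", cmp2$intronic)
})
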