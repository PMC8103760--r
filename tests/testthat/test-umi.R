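test_that("directional collapse absorbs neighbours by the 2n-1 count rule", {
  r <- directional_umi_collapse(c(AAAA = 10L, AAAT = 1L))
  expect_equal(unname(r[c("AAAA", "AAAT")]), c("AAAA", "AAAA"))
  # boundary: 5 >= 2*3 - 1
  r <- directional_umi_collapse(c(AAAA = 5L, AAAT = 3L))
  expect_equal(unname(unique(r)), "AAAA")
  # just below the boundary: 5 < 2*4 - 1
  r <- directional_umi_collapse(c(AAAA = 5L, AAAT = 4L))
  expect_equal(length(unique(r)), 2L)
  # Hamming distance 4: never merged
  r <- directional_umi_collapse(c(AAAA = 5L, TTTT = 5L))
  expect_equal(length(unique(r)), 2L)
})

test_that("directional collapse equals the brute-force graph oracle", {
  set.seed(13)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    umis <- unique(vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C"), 6, replace = TRUE), collapse = "")
    }, character(1)))  # two-letter alphabet makes Hamming-1 pairs common
    counts <- setNames(sample(1:12, length(umis), replace = TRUE), umis)
    got <- directional_umi_collapse(counts)
    want <- oracle_directional(counts)
    expect_equal(got[names(want)], want)
  }
  # permutation invariance of the resulting partition
  counts <- c(AACACA = 9L, AACACC = 4L, AACACG = 2L, TTTTTT = 5L)
  p1 <- directional_umi_collapse(counts)
  p2 <- directional_umi_collapse(rev(counts))
  expect_equal(p1[sort(names(p1))], p2[sort(names(p2))])
})

test_that("PCR duplicates are reads at identical mapping positions", {
  r <- count_pcr_duplicates(rep("c1", 3), rep(10L, 3), rep("50M", 3),
                            rep("+", 3))
  expect_equal(r$n_unique_positions, 1L)
  expect_equal(r$n_pcr_duplicates, 2L)
  r <- count_pcr_duplicates(rep("c1", 3), c(10L, 20L, 30L), rep("50M", 3),
                            rep("+", 3))
  expect_equal(r$n_unique_positions, 3L)
  expect_equal(r$n_pcr_duplicates, 0L)
  # mixed multiset against a pairwise-comparison oracle
  set.seed(4)
  pos <- sample(1:4, 20, replace = TRUE)
  cig <- sample(c("50M", "40M10S"), 20, replace = TRUE)
  r <- count_pcr_duplicates(rep("c1", 20), pos, cig, rep("+", 20))
  uniq <- nrow(unique(data.frame(pos, cig)))
  expect_equal(r$n_unique_positions, uniq)
  expect_equal(r$n_pcr_duplicates, 20L - uniq)
})

test_that("splice status and UMI-gene conflicts follow the printed rules", {
  expect_equal(assign_splice_status(rep("exonic", 5)), "spliced")
  expect_equal(assign_splice_status(c(rep("exonic", 4), "intronic")),
               "unspliced")
  expect_equal(assign_splice_status("intronic"), "unspliced")

  reads <- data.table::data.table(
    read_id = 1:10,
    barcode = "BC1",
    gene_id = c(rep("gA", 5), rep("gB", 2), rep("gC", 3)),
    umi = c(rep("AAAA", 7), rep("CCCC", 3)),
    annotation = "exonic",
    contig = "c1", pos = 1:10, cigar = "50M", strand = "+")
  ug <- build_umi_groups(reads)
  # AAAA maps to gA (5 reads) and gB (2): gA retained
  expect_equal(sort(ug$groups$gene_id), c("gA", "gC"))
  expect_equal(ug$n_conflict_discarded, 1L)
  # exact tie discards both
  reads2 <- data.table::data.table(
    read_id = 1:6, barcode = "BC1",
    gene_id = rep(c("gA", "gB"), each = 3),
    umi = "AAAA", annotation = "exonic",
    contig = "c1", pos = 1:6, cigar = "50M", strand = "+")
  ug2 <- build_umi_groups(reads2)
  expect_equal(nrow(ug2$groups), 0L)
  # a UMI seen in one gene only is kept
  ug3 <- build_umi_groups(reads[gene_id == "gC"])
  expect_equal(nrow(ug3$groups), 1L)
})

test_that("saturation and PCR duplicate rates reduce to their formulas", {
  # every molecule sequenced exactly 4 times at one position
  reads <- data.table::data.table(
    read_id = 1:8, barcode = "BC1",
    gene_id = rep(c("g1", "g2"), each = 4),
    umi = rep(c("AAAA", "TTTT"), each = 4),
    annotation = "exonic", contig = "c1",
    pos = rep(c(5L, 900L), each = 4), cigar = "50M", strand = "+")
  ug <- build_umi_groups(reads)
  m <- compute_barcode_metrics(reads, ug$groups)
  expect_equal(m$saturation, 0.75)
  expect_equal(m$pcr_duplicate_rate, 0.75)
  # no duplicates at all
  reads2 <- data.table::data.table(
    read_id = 1:4, barcode = "BC1", gene_id = paste0("g", 1:4),
    umi = c("AAAA", "TTTT", "GGGG", "CCCC"),
    annotation = "exonic", contig = "c1",
    pos = c(1L, 500L, 1000L, 1500L) * 10L, cigar = "50M", strand = "+")
  ug2 <- build_umi_groups(reads2)
  m2 <- compute_barcode_metrics(reads2, ug2$groups)
  expect_equal(m2$saturation, 0)
  expect_equal(m2$pcr_duplicate_rate, 0)
  # a barcode with zero countable reads gets NA rates
  reads3 <- data.table::data.table(
    read_id = 1L, barcode = "BC2", gene_id = NA_character_,
    umi = "AAAA", annotation = "intergenic", contig = "c1",
    pos = 1L, cigar = "50M", strand = "+")
  m3 <- compute_barcode_metrics(rbind(reads2, reads3), ug2$groups)
  expect_true(is.na(m3[barcode == "BC2", saturation]))
})

test_that("planted duplication rates are recovered exactly from synthesis", {
  d <- tiny_dataset()
  ann <- d$lib$reads[, .(read_id, barcode, umi, gene_id, contig, pos, cigar,
                         strand)]
  ann[, annotation := "exonic"]
  tr_mols <- d$lib$truth$molecules
  ann[d$lib$reads[, .(read_id, mol_id)], on = "read_id", mol_id := i.mol_id]
  ann[tr_mols, on = "mol_id", annotation := fifelse(i.intronic, "intronic",
                                                    "exonic")]
  ug <- build_umi_groups(ann)
  m <- compute_barcode_metrics(ann, ug$groups)
  tr <- d$lib$truth$barcodes
  cmp <- merge(m, tr, by = "barcode")
  expect_equal(cmp$saturation.x, cmp$saturation.y)
  expect_equal(cmp$pcr_duplicate_rate.x, cmp$pcr_duplicate_rate.y)
  expect_equal(cmp$molecules.x, cmp$molecules.y)
  # matrix row sums equal per-barcode molecule counts
  mats <- count_matrix(ug$groups)
  tot <- Matrix::colSums(mats$spliced) + Matrix::colSums(mats$unspliced)
  expect_equal(unname(tot[cmp$barcode]), cmp$molecules.y)
})

test_that("gene-list molecule percentages land on the metrics table", {
  reads <- data.table::data.table(
    read_id = 1:4, barcode = "BC1", gene_id = c("mt1", "g2", "g3", "g4"),
    umi = c("AAAA", "TTTT", "GGGG", "CCCC"), annotation = "exonic",
    contig = "c1", pos = c(1L, 5000L, 10000L, 15000L), cigar = "50M",
    strand = "+")
  ug <- build_umi_groups(reads)
  m <- compute_barcode_metrics(reads, ug$groups, gene_lists = list(mt = "mt1"))
  expect_equal(m$mt_molecules, 1L)
  expect_equal(m$mt_pct, 25)
})
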