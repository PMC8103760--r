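test_that("site labelling against DNA evidence follows the TP/FP/FN rules", {
  calls <- data.table::data.table(
    contig = "c1", pos = c(10L, 20L, 30L), alt = "G",
    n_barcodes = c(10L, 10L, 10L))
  dna <- data.table::data.table(
    contig = "c1", pos = c(10L, 20L, 40L, 50L),
    dna_coverage = c(30L, 20L, 40L, 10L),
    dna_alt_count = c(10L, 0L, 8L, 9L))
  cov <- data.table::data.table(contig = "c1", pos = c(40L, 50L),
                                n_barcodes = c(6L, 4L))
  lab <- label_sites(calls, dna, cov)
  get <- function(p) lab[pos == p, label]
  expect_equal(get(10L), "TP")              # called, 10 alt DNA reads
  expect_equal(get(20L), "FP")              # called, covered, 0 alt
  expect_equal(get(40L), "FN")              # DNA-supported, 6 barcodes
  expect_equal(length(get(50L)), 0L)        # DNA coverage below 15: excluded
  # a called site without DNA coverage is excluded from labelling
  expect_false(30L %in% lab$pos)
  # FN needs at least 5 covering barcodes
  cov2 <- data.table::data.table(contig = "c1", pos = 40L, n_barcodes = 4L)
  lab2 <- label_sites(calls, dna, cov2)
  expect_false("FN" %in% lab2$label)
})

test_that("bulk accuracy reduces to the TPR/FDR/F1 formulas", {
  lab <- data.table::data.table(label = c(rep("TP", 9), "FP", "FN"))
  acc <- bulk_accuracy(lab)
  expect_equal(acc$tpr, 0.9)
  expect_equal(acc$fdr, 0.1)
  expect_equal(acc$f1, 0.9)
  expect_equal(bulk_accuracy(data.table::data.table(label = "TP"))$fdr, 0)
  # random labels against direct recomputation
  set.seed(31)
  for (i in 1:10) {
    lab <- data.table::data.table(
      label = sample(c("TP", "FP", "FN"), 50, replace = TRUE))
    acc <- bulk_accuracy(lab)
    tp <- sum(lab$label == "TP"); fp <- sum(lab$label == "FP")
    fn <- sum(lab$label == "FN")
    expect_equal(acc$tpr, tp / (tp + fn))
    expect_equal(acc$f1, 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("raising the MAF cutoff never increases TP or FP", {
  set.seed(33)
  calls <- data.table::data.table(
    contig = "c1", pos = seq(10L, 300L, by = 10L), alt = "G",
    n_barcodes = 10L, maf = runif(30))
  dna <- data.table::data.table(
    contig = "c1", pos = seq(10L, 300L, by = 10L),
    dna_coverage = 30L,
    dna_alt_count = sample(c(0L, 10L), 30, replace = TRUE))
  sweep <- maf_sweep(calls, dna, cutoffs = c(0, 0.2, 0.4, 0.6, 0.8))
  expect_true(all(diff(sweep$n_tp) <= 0))
  expect_true(all(diff(sweep$n_fp) <= 0))
})

test_that("per-cell accuracy separates FN[bulk] from FN[cell]", {
  truth <- data.table::data.table(contig = "c1", pos = 1:10, alt = "G")
  # cell C1 covers all 10 sites, alt at 8, ref-only at 2
  cc <- data.table::data.table(
    contig = "c1",
    pos = c(1:10, 1:8),
    barcode = "C1",
    base = c(rep("A", 10), rep("G", 8)),
    count = 1L)
  per <- per_cell_accuracy(cc, truth, cells = c("C1", "C2"))
  expect_equal(per[barcode == "C1", tpr_cell], 0.8)
  expect_equal(per[barcode == "C1", fn_cell], 2L)
  expect_equal(per[barcode == "C1", fn_bulk], 2L)
  # C2 covers nothing: all truth sites are FN[bulk], none FN[cell]
  expect_equal(per[barcode == "C2", fn_bulk], 10L)
  expect_equal(per[barcode == "C2", fn_cell], 0L)
  expect_true(is.na(per[barcode == "C2", tpr_cell]))
})

test_that("the homozygous-SNV simulator honours its constraints", {
  set.seed(35)
  g <- Biostrings::DNAStringSet(paste(sample(c("A", "C", "G", "T"), 500,
                                             replace = TRUE), collapse = ""))
  names(g) <- "cs"
  cov <- data.table::data.table(contig = "cs", pos = 0:499,
                                cov = c(rep(10L, 200), rep(2L, 300)))
  excl <- data.table::data.table(contig = "cs", pos = c(50L, 150L))
  sim <- simulate_homozygous_snvs(g, cov, excl, n = 30L, seed = 9L)
  expect_equal(nrow(sim$truth), 30L)
  # >= 10 bp from every exclusion, >= 5X coverage
  expect_true(all(abs(outer(sim$truth$pos, excl$pos, "-")) >= 10L))
  expect_true(all(sim$truth$pos < 200L))
  # planted base differs from the reference and the genome is modified there
  modseq <- as.character(sim$genome[["cs"]])
  expect_true(all(sim$truth$alt != sim$truth$ref))
  expect_equal(substring(modseq, sim$truth$pos + 1L, sim$truth$pos + 1L),
               sim$truth$alt)
  # deterministic under the seed
  sim2 <- simulate_homozygous_snvs(g, cov, excl, n = 30L, seed = 9L)
  expect_identical(sim$truth, sim2$truth)
  # a position 9 bp from an exclusion is never sampled even when forced
  cov3 <- data.table::data.table(contig = "cs", pos = c(59L, 100L, 120L),
                                 cov = 10L)
  sim3 <- simulate_homozygous_snvs(g, cov3, excl, n = 2L, seed = 1L)
  expect_false(59L %in% sim3$truth$pos)
  # too few eligible positions errors with the count
  expect_error(simulate_homozygous_snvs(g, cov3, excl, n = 5L, seed = 1L),
               "eligible")
})

test_that("simulated-truth labels use coverage from either genome", {
  truth <- data.table::data.table(contig = "c1", pos = c(5L, 15L, 25L),
                                  alt = "G")
  cc <- data.table::data.table(
    contig = "c1", pos = c(5L, 15L), barcode = "C1",
    base = c("G", "A"), count = 1L)
  # site 25 covered only in the unmodified run
  unmod <- data.table::data.table(contig = "c1", pos = 25L, barcode = "C1")
  per <- sim_truth_labels(cc, unmod, truth, cells = "C1")
  expect_equal(per$n_tp, 1L)   # pos 5: alt expressed
  expect_equal(per$n_fn, 2L)   # pos 15: covered, ref only; pos 25: unmod-only
  # no unmodified-coverage: only the modified-run FN remains
  per2 <- sim_truth_labels(cc, NULL, truth, cells = "C1")
  expect_equal(per2$n_fn, 1L)
})
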