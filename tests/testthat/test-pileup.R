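# a tiny flat genome for constructed pileups
flat_genome <- function(len = 300L, base = "A") {
  g <- Biostrings::DNAStringSet(strrep(base, len))
  names(g) <- "cf"
  g
}

test_that("pileup counts match a naive per-base walk", {
  set.seed(23)
  g <- Biostrings::DNAStringSet(paste(sample(c("A", "C", "G", "T"), 400,
                                             replace = TRUE), collapse = ""))
  names(g) <- "cf"
  n <- 40
  rec <- mk_records(
    contig = "cf",
    pos = sample(0:300, n, replace = TRUE),
    cigar = sample(c("40M", "20M30N20M"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    seq = vapply(1:n, function(i) paste(sample(c("A", "C", "G", "T"), 40,
                                               replace = TRUE), collapse = ""),
                 character(1)),
    qual = vapply(1:n, function(i) qual_str(sample(15:40, 1), 40), character(1)),
    barcode = sample(c("B1", "B2", "B3"), n, replace = TRUE))
  pu <- pileup(rec, g, params = snv_filter_params(), dialect = "tags")
  want <- oracle_pileup(rec, g, min_bq = 20L)
  for (i in seq_len(nrow(pu$sites))) {
    key <- paste(pu$sites$contig[i], pu$sites$pos[i])
    col <- want[[key]]
    expect_equal(pu$sites$total_bases[i], nrow(col))
    expect_equal(pu$sites$n_barcodes[i], length(unique(col$barcode)))
    expect_equal(pu$sites$plus_mols[i], sum(col$strand == "+"))
    ref <- pu$sites$ref[i]
    alts <- pu$alleles[contig == pu$sites$contig[i] & pos == pu$sites$pos[i]]
    for (j in seq_len(nrow(alts))) {
      expect_equal(alts$alt_bases[j], sum(col$base == alts$alt[j]))
      expect_equal(alts$n_barcodes_alt[j],
                   length(unique(col$barcode[col$base == alts$alt[j]])))
    }
  }
})

test_that("base quality below 20 is never counted", {
  g <- flat_genome()
  rec <- mk_records("cf", c(10L, 10L, 10L), "30M", "+",
                    c(paste0(strrep("A", 15), "G", strrep("A", 14)),
                      strrep("A", 30), strrep("A", 30)),
                    c(qual_str(19, 30), qual_str(30, 30), qual_str(30, 30)),
                    c("B1", "B2", "B3"))
  pu <- pileup(rec, g, dialect = "tags")
  expect_equal(nrow(pu$sites), 0L)  # the only mismatch is below quality
  # the same mismatch at quality 20 is counted: ref 2 / alt 1
  rec$qual[1] <- qual_str(20, 30)
  pu <- pileup(rec, g, dialect = "tags")
  expect_equal(nrow(pu$sites), 1L)
  expect_equal(pu$sites$ref_bases, 2L)
  expect_equal(pu$alleles$alt_bases, 1L)
})

test_that("SNV filters are each decisive at their printed thresholds", {
  g <- flat_genome()
  mk <- function(n_cov, n_alt, mm_off = 15L) {
    # n_cov barcodes each with one 30 bp molecule over [10,40); n_alt of them
    # carry G at offset mm_off
    seqs <- c(rep(paste0(strrep("A", mm_off), "G",
                         strrep("A", 29L - mm_off)), n_alt),
              rep(strrep("A", 30), n_cov - n_alt))
    mk_records("cf", rep(10L, n_cov), "30M", "+", seqs,
               rep(qual_str(30, 30), n_cov), sprintf("B%02d", seq_len(n_cov)))
  }
  p <- snv_filter_params()
  # 5 barcodes, 2 alt, central mismatch: called
  calls <- call_snvs(pileup(mk(5, 2), g, dialect = "tags"), p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$alt, "G")
  # 4 barcodes covered: rejected
  expect_equal(nrow(call_snvs(pileup(mk(4, 2), g, dialect = "tags"), p)), 0L)
  # 1 alt barcode: rejected
  expect_equal(nrow(call_snvs(pileup(mk(5, 1), g, dialect = "tags"), p)), 0L)
  # all mismatches within 5 bp of a read end: rejected
  expect_equal(nrow(call_snvs(pileup(mk(5, 2, mm_off = 3L), g,
                                     dialect = "tags"), p)), 0L)
  # mismatch exactly 5 bp from the end: outside the excluded zone, called
  expect_equal(nrow(call_snvs(pileup(mk(5, 2, mm_off = 5L), g,
                                     dialect = "tags"), p)), 1L)
  # minor allele fraction below 0.01: rejected (2 alt bases of 250)
  big <- mk(250, 2)
  expect_equal(nrow(call_snvs(pileup(big, g, dialect = "tags"), p)), 0L)
})

test_that("internal read-ends of collapsed molecules count as read ends", {
  g <- flat_genome()
  # one molecule spanning [0, 200) with an internal end at 100; a mismatch at
  # 103 is within 5 bp of it
  seqs <- paste0(strrep("A", 103), "G", strrep("A", 96))
  rec <- mk_records("cf", rep(0L, 5), "200M", "+",
                    c(seqs, seqs, rep(strrep("A", 200), 3)),
                    rep(qual_str(30, 200), 5), sprintf("B%d", 1:5),
                    internal_ends = list(100L, 100L, integer(0), integer(0),
                                         integer(0)))
  pu <- pileup(rec, g, dialect = "collapsed")
  expect_equal(pu$alleles$max_end_dist, 3L)
  expect_equal(nrow(call_snvs(pu)), 0L)
  # without the internal ends the same mismatch is 96 bp from a read end
  rec$internal_ends <- rep(list(integer(0)), 5)
  pu2 <- pileup(rec, g, dialect = "collapsed")
  expect_equal(pu2$alleles$max_end_dist, 96L)
  expect_equal(nrow(call_snvs(pu2)), 1L)
})

test_that("allele-fraction cutoff, bi-allelic and strand refinement", {
  calls <- data.table::data.table(maf = c(0.30, 0.25, 0.01))
  expect_equal(apply_af_cutoff(calls)$maf, 0.30)  # strict >
  expect_equal(refine_biallelic(80L, 16L, 100L), TRUE)   # 96 of 100
  expect_equal(refine_biallelic(80L, 14L, 100L), FALSE)  # 94 of 100
  expect_equal(refine_biallelic(1L, 0L, 1L), TRUE)       # depth 1
  expect_equal(infer_strand(95L, 5L), "+")
  expect_equal(infer_strand(60L, 40L), "unknown")
  expect_equal(infer_strand(0L, 1L), "-")  # single molecule keeps its strand
  expect_equal(infer_strand(89L, 11L), "unknown")  # just under 90%
})

test_that("edit annotation is strand-oriented A>G in catalogue or repeat", {
  calls <- data.table::data.table(
    contig = "cf", pos = c(10L, 20L, 30L, 40L),
    ref = c("A", "T", "C", "A"), alt = c("G", "C", "T", "G"),
    alt_bases = 10L, ref_bases = 90L, total_bases = 100L,
    plus_mols = c(100L, 0L, 100L, 100L), minus_mols = c(0L, 100L, 0L, 0L),
    maf = 0.1)
  cat <- data.table::data.table(contig = "cf", pos = c(20L))
  rep_iv <- data.table::data.table(contig = "cf", start = 5L, end = 15L)
  ann <- annotate_calls(calls, edit_catalogue = cat, repeats = rep_iv)
  # plus-strand A>G inside the repeat interval
  expect_true(ann[pos == 10L, is_edit])
  # minus-strand read as T>C on the reference, in the catalogue
  expect_true(ann[pos == 20L, is_edit])
  expect_equal(ann[pos == 20L, strand], "-")
  # C>T in no catalogue: unknown
  expect_false(ann[pos == 30L, is_edit])
  expect_equal(ann[pos == 30L, annotation], "unknown")
  # A>G outside catalogue and repeats is not an edit
  expect_false(ann[pos == 40L, is_edit])
  # germline precedence over the edit class
  ann2 <- annotate_calls(calls, edit_catalogue = cat, repeats = rep_iv,
                         germline = data.table::data.table(
                           contig = "cf", pos = 10L, alt = "G"))
  expect_equal(ann2[pos == 10L, annotation], "germline")
})

test_that("known-site quantification is unfiltered and per cell", {
  g <- flat_genome()
  rec <- mk_records("cf", c(10L, 10L, 60L), "30M", "+",
                    c(paste0(strrep("A", 15), "G", strrep("A", 14)),
                      strrep("A", 30), strrep("A", 30)),
                    rep(qual_str(30, 30), 3), c("B1", "B1", "B2"))
  sites <- data.table::data.table(contig = "cf", pos = c(25L, 250L),
                                  alt = c("G", "C"))
  q <- quantify_known(rec, g, sites, cells = c("B1", "B2"))
  # het cell: one ref and one alt molecule
  expect_equal(unname(q$matrices$ref["cf:25", ]), c(1, 0))
  expect_equal(unname(q$matrices$alt["cf:25", ]), c(1, 0))
  # uncovered site stays empty
  expect_equal(sum(q$matrices$ref["cf:250", ]), 0)
  # out-of-reference sites are skipped with a warning
  expect_warning(
    quantify_known(rec, g, data.table::data.table(contig = "cf",
                                                  pos = c(25L, 9999L)),
                   cells = c("B1", "B2")),
    "skipped")
})

test_that("per-cell counts sum to the pseudo-bulk counts", {
  d <- tiny_dataset()
  run <- run_pipeline(d$lib$reads, d$index, expected_cells = d$cfg$n_cells)
  pu <- run$pileup
  agg <- pu$cell_counts[, .(n = sum(count)), by = .(contig, pos)]
  cmp <- merge(agg, pu$sites, by = c("contig", "pos"))
  expect_equal(cmp$n, cmp$total_bases)
})

test_that("co-expression sets report dominant type and purity", {
  base_obs <- data.table::data.table(
    rec_id = c(rep(1L, 5), rep(2L, 4)),
    contig = "cf",
    pos = c(1L, 2L, 3L, 4L, 5L, 1L, 2L, 3L, 4L),
    base = "G", qual = 30L, barcode = "B1", strand = "+", ref = "A",
    end_dist = 10L)
  calls <- data.table::data.table(
    contig = "cf", pos = 1:5, alt = "G",
    annotation = c("AG_edit", "AG_edit", "AG_edit", "unknown", "unknown"))
  sets <- extract_coexpression(base_obs, calls, min_snvs = 5L)
  # molecule 2 carries only 4 SNVs: excluded
  expect_equal(nrow(sets), 1L)
  expect_equal(sets$n_snvs, 5L)
  expect_equal(sets$dominant_type, "AG_edit")
  expect_equal(sets$purity, 0.6)
  # without a majority there is no dominant type
  calls2 <- data.table::copy(calls)[, annotation := c("AG_edit", "AG_edit",
                                                      "unknown", "unknown",
                                                      "germline")]
  sets2 <- extract_coexpression(base_obs, calls2, min_snvs = 5L)
  expect_true(is.na(sets2$dominant_type))
})
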