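# Benchmarking against matched DNA evidence: pseudo-bulk TP/FP/FN labelling,
# TPR/FDR/F1, per-cell accuracy under the FN[bulk]/FN[cell] definitions, and
# homozygous-SNV simulation by reference modification.

#' Label called sites against matched DNA evidence
#'
#' Sites are first restricted to positions with dscRNA coverage (at least one
#' qualifying base) and DNA coverage of at least `min_dna_coverage` reads
#' (mapping and base quality filters are assumed already applied to the DNA
#' evidence). A site carries DNA support when it has at least
#' `min_dna_alt` alternative bases. Labels: TP = called in dscRNA with DNA
#' support; FP = called in dscRNA, DNA-covered, without DNA support;
#' FN = DNA-supported, not called, and covered by at least `min_fn_barcodes`
#' cell barcodes in the dscRNA data.
#'
#' @param calls dscRNA calls (`contig`, `pos`, `alt`, `n_barcodes`)
#' @param dna data.table of DNA evidence: `contig`, `pos`, `dna_coverage`,
#'   `dna_alt_count` and optionally `alt` and `dna_called` (a DNA caller's
#'   verdict; when absent the >=2-alt-reads rule stands in for it)
#' @param dsc_coverage data.table (`contig`, `pos`, `n_barcodes`) giving
#'   dscRNA barcode coverage at DNA-supported sites not called in dscRNA
#'   (needed to decide FN eligibility); calls provide their own coverage
#' @param min_dna_coverage default 15
#' @param min_dna_alt default 2
#' @param min_fn_barcodes default 5
#' @return data.table of labelled sites with a `label` column in
#'   `c("TP", "FP", "FN")`; called sites without DNA coverage are excluded
#' @export
label_sites <- function(calls, dna, dsc_coverage = NULL,
                        min_dna_coverage = 15L, min_dna_alt = 2L,
                        min_fn_barcodes = 5L) {
  calls <- as.data.table(calls)
  dna <- copy(as.data.table(dna))
  dna <- dna[dna_coverage >= min_dna_coverage]
  if (!"dna_called" %in% names(dna)) {
    dna[, dna_called := dna_alt_count >= min_dna_alt]
  }
  dna[, dna_present := dna_alt_count >= min_dna_alt]

  lab <- merge(calls[, .(contig, pos, alt, n_barcodes, called = TRUE)],
               dna, by = c("contig", "pos"),
               all = TRUE, suffixes = c("", ".dna"))
  lab[is.na(called), called := FALSE]
  # called sites with no (sufficient) DNA coverage are excluded
  lab <- lab[!(called & is.na(dna_present))]
  lab[is.na(dna_present), dna_present := FALSE]

  if (!is.null(dsc_coverage)) {
    lab[as.data.table(dsc_coverage), on = c("contig", "pos"),
        n_barcodes := fifelse(is.na(n_barcodes), i.n_barcodes, n_barcodes)]
  }
  lab[, label := NA_character_]
  lab[called & dna_present, label := "TP"]
  lab[called & !dna_present, label := "FP"]
  lab[!called & dna_called & !is.na(n_barcodes) & n_barcodes >= min_fn_barcodes,
      label := "FN"]
  lab[!is.na(label)]
}

#' Pseudo-bulk accuracy from site labels
#'
#' @param labels data.table with a `label` column (`TP`/`FP`/`FN`)
#' @return list with `n_tp`, `n_fp`, `n_fn`, `tpr = TP/(TP+FN)`,
#'   `fdr = FP/(TP+FP)`, `f1 = 2TP/(2TP+FP+FN)`; rates are `NA` when their
#'   denominator is zero
#' @export
bulk_accuracy <- function(labels) {
  lab <- as.data.table(labels)$label
  tp <- sum(lab == "TP"); fp <- sum(lab == "FP"); fn <- sum(lab == "FN")
  list(n_tp = tp, n_fp = fp, n_fn = fn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}

#' Accuracy across a sweep of allele-fraction cutoffs
#'
#' Re-labels with calls restricted to `maf > cutoff` for each cutoff; useful
#' for locating the TPR-vs-FDR elbow.
#'
#' @param calls calls with a `maf` column
#' @param dna,dsc_coverage,... passed to [label_sites()]
#' @param cutoffs numeric vector of allele-fraction cutoffs
#' @return data.table with one row per cutoff: counts plus `tpr`, `fdr`, `f1`
#' @export
maf_sweep <- function(calls, dna, dsc_coverage = NULL,
                      cutoffs = seq(0, 0.5, by = 0.05), ...) {
  rbindlist(lapply(cutoffs, function(co) {
    acc <- bulk_accuracy(label_sites(as.data.table(calls)[maf > co],
                                     dna, dsc_coverage, ...))
    c(list(cutoff = co), acc)
  }))
}

#' Per-cell accuracy at truth sites
#'
#' For each cell: TP = truth sites with at least one alternative molecule;
#' FN[bulk] = truth sites with only reference counts or no coverage in that
#' cell; FN[cell] = truth sites with coverage (at least `min_coverage`
#' molecules) but zero alternative molecules. TPR is reported under both
#' definitions, plus the per-cell FDR over called-and-expressed non-truth
#' sites when `calls` is given.
#'
#' @param cell_counts long per-cell counts (`contig`, `pos`, `barcode`,
#'   `base`, `count`) from [pileup()]/[quantify_known()]
#' @param truth data.table of truth sites (`contig`, `pos`, `alt`)
#' @param cells character vector of cell barcodes to evaluate
#' @param calls optional dscRNA calls for the per-cell FDR
#' @param min_coverage coverage needed before a site counts as covered
#'   (default 1)
#' @return data.table, one row per cell: `n_tp`, `fn_bulk`, `fn_cell`,
#'   `tpr_bulk`, `tpr_cell`, `fdr`, `n_covered`
#' @export
per_cell_accuracy <- function(cell_counts, truth, cells, calls = NULL,
                              min_coverage = 1L) {
  cc <- as.data.table(cell_counts)
  truth <- as.data.table(truth)
  n_truth <- nrow(truth)
  tc <- merge(cc, truth, by = c("contig", "pos"))
  stat <- tc[, .(cov = sum(count), alt_count = sum(count[base == alt])),
             by = .(contig, pos, barcode)]
  per <- stat[, .(
    n_covered = sum(cov >= min_coverage),
    n_tp = sum(alt_count >= 1L & cov >= min_coverage),
    fn_cell = sum(cov >= min_coverage & alt_count == 0L)
  ), by = barcode]
  all_cells <- data.table(barcode = cells)
  per <- merge(all_cells, per, by = "barcode", all.x = TRUE)
  for (cc2 in c("n_covered", "n_tp", "fn_cell")) {
    per[is.na(get(cc2)), (cc2) := 0L]
  }
  per[, fn_bulk := n_truth - n_tp]
  per[, tpr_bulk := if (n_truth > 0L) n_tp / n_truth else NA_real_]
  per[, tpr_cell := fifelse(n_tp + fn_cell > 0L, n_tp / (n_tp + fn_cell),
                            NA_real_)]
  if (!is.null(calls)) {
    nt <- merge(cc, as.data.table(calls)[, .(contig, pos, alt)],
                by = c("contig", "pos"))
    nt <- nt[!truth, on = c("contig", "pos")]
    fpc <- nt[base == alt, .(n_fp_cell = data.table::uniqueN(paste(contig, pos))),
              by = barcode]
    per[, n_fp_cell := 0L]
    per[fpc, on = "barcode", n_fp_cell := i.n_fp_cell]
    per[, fdr := fifelse(n_tp + n_fp_cell > 0L,
                         n_fp_cell / (n_tp + n_fp_cell), NA_real_)]
  }
  per[]
}

#' Mean per-cell TPR across coverage and allele-fraction cutoffs
#'
#' Grid version of [per_cell_accuracy()] under the FN[cell] definition: for
#' each coverage cutoff, sites in a cell count only when covered by at least
#' that many molecules; the mean per-cell TPR is reported.
#'
#' @param cell_counts,truth,cells as in [per_cell_accuracy()]
#' @param coverage_cutoffs integer vector (default 1:10)
#' @return data.table with `coverage_cutoff` and `mean_tpr`
#' @export
tpr_coverage_grid <- function(cell_counts, truth, cells,
                              coverage_cutoffs = 1:10) {
  rbindlist(lapply(coverage_cutoffs, function(co) {
    per <- per_cell_accuracy(cell_counts, truth, cells, min_coverage = co)
    data.table(coverage_cutoff = co,
               mean_tpr = mean(per$tpr_cell, na.rm = TRUE))
  }))
}

#' Simulate homozygous SNVs by modifying the reference genome
#'
#' Samples `n` positions uniformly, without replacement, among positions with
#' coverage of at least `min_coverage` and at least `min_distance` bases from
#' every exclusion call, then substitutes the reference base with a uniformly
#' chosen different base. Deterministic under `seed`.
#'
#' @param genome a [Biostrings::DNAStringSet]
#' @param coverage data.table (`contig`, `pos`, `cov`) from a pileup of the
#'   unmodified run
#' @param exclusions data.table (`contig`, `pos`) of SNV calls to stay away
#'   from
#' @param n number of SNVs to plant (default 25000)
#' @param min_distance minimum distance to any exclusion (default 10)
#' @param min_coverage minimum coverage of eligible positions (default 5)
#' @param seed RNG seed
#' @return list with `genome` (modified copy) and `truth` (data.table
#'   `contig`, `pos`, `ref`, `alt`, sorted)
#' @export
simulate_homozygous_snvs <- function(genome, coverage, exclusions = NULL,
                                     n = 25000L, min_distance = 10L,
                                     min_coverage = 5L, seed = 1L) {
  cov <- as.data.table(coverage)[cov >= min_coverage, .(contig, pos)]
  if (!is.null(exclusions) && nrow(exclusions)) {
    ex <- as.data.table(exclusions)
    cov[, d := Inf]
    for (ct in unique(cov$contig)) {
      e <- ex[contig == ct, pos]
      if (length(e)) cov[contig == ct, d := dist_to_nearest(pos, e)]
    }
    cov <- cov[d >= min_distance][, d := NULL]
  }
  if (nrow(cov) < n) {
    stop("only ", nrow(cov), " eligible positions for ", n, " simulated SNVs")
  }
  set.seed(seed)
  pick <- cov[sample.int(nrow(cov), n)]
  setorder(pick, contig, pos)
  pick[, ref := ref_chunks(genome, contig, pos, pos + 1L)]
  pick[, alt := vapply(ref, function(r) sample(setdiff(BASES, r), 1L),
                       character(1))]
  mod <- genome
  for (ct in unique(pick$contig)) {
    sub <- pick[contig == ct]
    mod[[ct]] <- Biostrings::replaceLetterAt(
      mod[[ct]], sub$pos + 1L, paste(sub$alt, collapse = ""))
  }
  list(genome = mod, truth = pick[])
}

#' Per-cell truth labels for simulated homozygous SNVs
#'
#' A cell/site pair is TP when at least one alternative molecule is observed;
#' FN when no alternative molecule is observed but the pair has detectable
#' coverage in either the modified-genome alignment or the original
#' unmodified-genome alignment (catching coverage lost to alignment artefacts
#' around the planted base).
#'
#' @param cell_counts_mod per-cell counts at truth sites from the
#'   modified-genome run (long format as in [per_cell_accuracy()])
#' @param coverage_unmod data.table (`contig`, `pos`, `barcode`) marking
#'   cell/site pairs covered in the unmodified-genome run
#' @param truth the simulator truth table
#' @param cells cell barcodes
#' @return data.table per cell: `n_tp`, `n_fn`, `tpr`
#' @export
sim_truth_labels <- function(cell_counts_mod, coverage_unmod, truth, cells) {
  cc <- merge(as.data.table(cell_counts_mod), as.data.table(truth),
              by = c("contig", "pos"))
  pair <- cc[, .(cov = sum(count), alt_count = sum(count[base == alt])),
             by = .(contig, pos, barcode)]
  if (!is.null(coverage_unmod) && nrow(coverage_unmod)) {
    extra <- as.data.table(coverage_unmod)[, .(contig, pos, barcode)]
    extra <- merge(extra, as.data.table(truth)[, .(contig, pos)],
                   by = c("contig", "pos"))
    pair <- merge(pair, unique(extra)[, covered_unmod := TRUE],
                  by = c("contig", "pos", "barcode"), all = TRUE)
    pair[is.na(cov), `:=`(cov = 0L, alt_count = 0L)]
    pair[is.na(covered_unmod), covered_unmod := FALSE]
  } else {
    pair[, covered_unmod := FALSE]
  }
  pair <- pair[barcode %in% cells]
  per <- pair[, .(
    n_tp = sum(alt_count >= 1L),
    n_fn = sum(alt_count == 0L & (cov >= 1L | covered_unmod))
  ), by = barcode]
  per[, tpr := fifelse(n_tp + n_fn > 0L, n_tp / (n_tp + n_fn), NA_real_)]
  per[]
}
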