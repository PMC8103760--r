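# End-to-end driver chaining the post-alignment steps: read annotation,
# directional UMI grouping, consensus collapsing, per-barcode metrics, cell
# calling, pileup and SNV calling/annotation.

#' Run the post-alignment pipeline on an alignment table
#'
#' Takes annotated-ready alignment records (one retained alignment per read,
#' e.g. gold alignments from [generate_library()] or records imported with
#' [read_alignments()]), classifies every read against the reference index,
#' groups countable reads into molecules by directional UMI collapsing,
#' collapses each group into a consensus molecule, computes per-barcode
#' metrics, calls cells, and runs the strand/barcode-aware pileup with SNV
#' filters over the cells' collapsed molecules.
#'
#' @param reads data.table with `read_id`, `barcode`, `umi`, `contig`, `pos`,
#'   `cigar`, `strand`, `seq`, `qual`, optional `source` and `was_corrected`
#' @param index a `ref_index`
#' @param expected_cells for the elbow estimate (default 3000)
#' @param gene_lists named list of gene-id vectors for list metrics (e.g.
#'   `list(mt = ...)`)
#' @param snv_params [snv_filter_params()]
#' @param consensus [consensus_params()]
#' @param cell_filters MAD filters to apply (see [call_cells()])
#' @param call_cells_first when FALSE, the pileup uses all barcodes instead of
#'   called cells
#' @return list of class `dropsnv_run` with elements `annotations`, `groups`,
#'   `molecules`, `metrics`, `matrices`, `cells`, `pileup`, `calls`
#' @export
run_pipeline <- function(reads, index,
                         expected_cells = 3000L,
                         gene_lists = list(),
                         snv_params = snv_filter_params(),
                         consensus = consensus_params(),
                         cell_filters = c("mt", "saturation", "pcr", "corrected"),
                         call_cells_first = TRUE) {
  reads <- as.data.table(reads)
  if (!"source" %in% names(reads)) reads[, source := "genome"]

  ann <- annotate_reads(reads[, .(read_id, contig, pos, cigar, strand, source)],
                        index)
  reads <- merge(reads[, setdiff(names(reads), c("annotation", "gene_id")),
                       with = FALSE],
                 ann, by = "read_id")

  ug <- build_umi_groups(reads)
  metrics <- compute_barcode_metrics(reads, ug$groups, gene_lists)
  mats <- count_matrix(ug$groups)
  cell_res <- call_cells(metrics, expected_cells = expected_cells,
                         filters = cell_filters)

  mol <- collapse_molecules(reads, ug$groups, ug$read_groups, consensus)

  pu_cells <- if (call_cells_first) cell_res$cells else NULL
  pu <- pileup(mol, index, cells = pu_cells, params = snv_params,
               dialect = "collapsed")
  calls <- call_snvs(pu, snv_params)

  structure(list(annotations = ann, groups = ug$groups, metrics = metrics,
                 matrices = mats, cells = cell_res, molecules = mol,
                 pileup = pu, calls = calls,
                 n_conflict_discarded = ug$n_conflict_discarded),
            class = "dropsnv_run")
}

#' @export
print.dropsnv_run <- function(x, ...) {
  cat("dropsnv_run:\n")
  cat("  reads annotated: ", nrow(x$annotations), "\n", sep = "")
  cat("  molecules:       ", nrow(x$molecules), "\n", sep = "")
  cat("  cells:           ", length(x$cells$cells), "\n", sep = "")
  cat("  SNV calls:       ", nrow(x$calls), "\n", sep = "")
  invisible(x)
}
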