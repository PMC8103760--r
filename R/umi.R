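# Directional UMI deduplication, PCR-duplicate counting, UMI-gene conflict
# resolution, per-barcode metrics and sparse count matrices.

#' Directional UMI collapse for one (barcode, gene) group
#'
#' Builds the directed graph with an edge from UMI `a` to UMI `b` when they
#' differ at exactly one base and `count(a) >= 2 * count(b) - 1`, then absorbs
#' UMIs reachable from unvisited root UMIs taken in descending count order
#' (ties broken lexicographically for determinism). Each resulting group is
#' labelled by its root UMI.
#'
#' @param counts named integer vector: UMI -> supporting read count
#' @return named character vector mapping each input UMI to its group root
#' @export
directional_umi_collapse <- function(counts) {
  umis <- names(counts)
  n <- length(umis)
  if (n == 0L) return(setNames(character(0), character(0)))
  if (n == 1L) return(setNames(umis, umis))
  o <- order(-counts, umis)
  umis <- umis[o]; counts <- counts[o]

  # adjacency: Hamming distance 1
  L <- nchar(umis[1])
  mat <- matrix(unlist(strsplit(umis, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  root <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(root[i])) next
    root[i] <- umis[i]
    queue <- i
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in seq_len(n)) {
        if (!is.na(root[b])) next
        if (sum(mat[a, ] != mat[b, ]) != 1L) next
        if (counts[a] >= 2L * counts[b] - 1L) {
          root[b] <- umis[i]
          queue <- c(queue, b)
        }
      }
    }
  }
  setNames(root, umis)
}

#' Assign corrected UMIs to countable reads
#'
#' Applies [directional_umi_collapse()] within every (barcode, gene) pair.
#' Groups with a single observed UMI are passed through unchanged.
#'
#' @param reads data.table with columns `barcode`, `gene_id`, `umi`
#' @return the input with an added `umi_corrected` column
#' @export
correct_umis <- function(reads) {
  reads <- copy(as.data.table(reads))
  reads[, umi_corrected := umi]
  reads[, n_umi := data.table::uniqueN(umi), by = .(barcode, gene_id)]
  multi <- reads[n_umi > 1L]
  if (nrow(multi)) {
    map <- multi[, {
      cnt <- table(umi)
      m <- directional_umi_collapse(setNames(as.integer(cnt), names(cnt)))
      .(umi = names(m), root = unname(m))
    }, by = .(barcode, gene_id)]
    reads[map, on = c("barcode", "gene_id", "umi"), umi_corrected := i.root]
  }
  reads[, n_umi := NULL]
  reads[]
}

#' Count PCR duplicates within a UMI group
#'
#' PCR duplicates are member reads sharing an identical mapping position
#' (contig, leftmost position, cigar, strand); reads at distinct positions are
#' molecular (UMI) duplicates from independent fragmentation.
#'
#' @param contig,pos,cigar,strand per-read alignment keys
#' @return list with `n_unique_positions` and `n_pcr_duplicates`
#' @export
count_pcr_duplicates <- function(contig, pos, cigar, strand) {
  key <- paste(contig, pos, cigar, strand, sep = "\r")
  u <- length(unique(key))
  list(n_unique_positions = u, n_pcr_duplicates = length(key) - u)
}

#' Splice status of a UMI group
#'
#' A group is unspliced if at least one member read was annotated intronic,
#' spliced otherwise.
#'
#' @param annotations character vector of member-read annotations
#' @return `"spliced"` or `"unspliced"`
#' @export
assign_splice_status <- function(annotations) {
  if (any(annotations == "intronic")) "unspliced" else "spliced"
}

#' Build UMI groups from countable reads
#'
#' Groups countable (exonic/intronic) reads by (barcode, gene, corrected UMI),
#' counts PCR duplicates and unique fragment positions, assigns splice status,
#' and resolves UMI-gene conflicts: when one corrected UMI maps to several
#' genes within a barcode, the gene with the most supporting reads is kept and
#' the others discarded; exact ties discard all of them.
#'
#' @param reads data.table with `read_id`, `barcode`, `gene_id`, `umi`,
#'   `annotation`, `contig`, `pos`, `cigar`, `strand`; only countable rows are
#'   used
#' @return list with `groups` (one row per retained molecule: `group_id`,
#'   `barcode`, `gene_id`, `umi`, `n_reads`, `n_unique_positions`,
#'   `n_pcr_duplicates`, `splice`), `read_groups` (read_id -> group_id for
#'   reads in retained groups) and `n_conflict_discarded`
#' @export
build_umi_groups <- function(reads) {
  reads <- as.data.table(reads)
  cr <- reads[annotation %in% c("exonic", "intronic")]
  cr <- correct_umis(cr)

  grp <- cr[, {
    pc <- count_pcr_duplicates(contig, pos, cigar, strand)
    .(n_reads = .N,
      n_unique_positions = pc$n_unique_positions,
      n_pcr_duplicates = pc$n_pcr_duplicates,
      splice = assign_splice_status(annotation))
  }, by = .(barcode, gene_id, umi_corrected)]

  # UMI-gene conflicts within a barcode
  grp[, n_genes := .N, by = .(barcode, umi_corrected)]
  conflict <- grp[n_genes > 1L]
  drop <- data.table(barcode = character(), gene_id = character(),
                     umi_corrected = character())
  if (nrow(conflict)) {
    drop <- conflict[, {
      m <- max(n_reads)
      w <- which(n_reads == m)
      keep <- if (length(w) == 1L) w else integer(0)
      .(gene_id = gene_id[setdiff(seq_len(.N), keep)])
    }, by = .(barcode, umi_corrected)]
  }
  n_drop <- nrow(drop)
  if (n_drop) {
    grp <- grp[!drop, on = c("barcode", "gene_id", "umi_corrected")]
  }
  grp[, n_genes := NULL]
  grp[, group_id := .I]
  setnames(grp, "umi_corrected", "umi")

  rg <- cr[, .(read_id, barcode, gene_id, umi_corrected)]
  setnames(rg, "umi_corrected", "umi")
  rg <- merge(rg, grp[, .(barcode, gene_id, umi, group_id)],
              by = c("barcode", "gene_id", "umi"))
  list(groups = grp[], read_groups = rg[, .(read_id, group_id)],
       n_conflict_discarded = n_drop)
}

#' Per-barcode library metrics
#'
#' Sequencing saturation is the fraction of countable reads that are molecular
#' duplicates: `(countable_reads - molecules) / countable_reads`. The PCR
#' duplicate rate divides PCR duplicates by countable reads. The corrected
#' read fraction comes from barcode-correction flags, and molecule counts are
#' reported for optional user gene lists (e.g. mitochondrial genes).
#'
#' @param reads all processed reads with `barcode`, `annotation`,
#'   `was_corrected` (missing column treated as all-FALSE)
#' @param groups retained UMI groups from [build_umi_groups()]
#' @param gene_lists named list of character vectors of gene ids
#' @return data.table, one row per barcode; barcodes with zero countable reads
#'   have `NA` rates
#' @export
compute_barcode_metrics <- function(reads, groups, gene_lists = list()) {
  reads <- as.data.table(reads)
  groups <- as.data.table(groups)
  if (!"was_corrected" %in% names(reads)) reads[, was_corrected := FALSE]

  ann <- data.table::dcast(
    reads[, .N, by = .(barcode, annotation)],
    barcode ~ annotation, value.var = "N", fill = 0L)
  for (a in READ_ANNOTATIONS) {
    if (!a %in% names(ann)) ann[, (a) := 0L]
  }
  ann[, countable_reads := exonic + intronic]

  corr <- reads[, .(corrected_read_fraction = mean(was_corrected)), by = barcode]
  gm <- groups[, .(
    molecules = .N,
    spliced_molecules = sum(splice == "spliced"),
    unspliced_molecules = sum(splice == "unspliced"),
    pcr_dups = sum(n_pcr_duplicates)
  ), by = barcode]

  out <- merge(ann, corr, by = "barcode", all = TRUE)
  out <- merge(out, gm, by = "barcode", all.x = TRUE)
  for (cc in c("molecules", "spliced_molecules", "unspliced_molecules", "pcr_dups")) {
    out[is.na(get(cc)), (cc) := 0L]
  }
  out[, saturation := fifelse(countable_reads > 0,
                              (countable_reads - molecules) / countable_reads,
                              NA_real_)]
  out[, pcr_duplicate_rate := fifelse(countable_reads > 0,
                                      pcr_dups / countable_reads, NA_real_)]
  for (nm in names(gene_lists)) {
    gl <- gene_lists[[nm]]
    cnt <- groups[gene_id %in% gl, .N, by = barcode]
    col <- paste0(nm, "_molecules")
    out[, (col) := 0L]
    out[cnt, on = "barcode", (col) := i.N]
    pcol <- paste0(nm, "_pct")
    out[, (pcol) := fifelse(molecules > 0, 100 * get(col) / molecules, 0)]
  }
  out[]
}

#' Sparse spliced/unspliced count matrices
#'
#' @param groups retained UMI groups
#' @param barcodes,genes axis orderings; defaults to the values present
#' @return list of two `dgCMatrix` (genes x barcodes): `spliced`, `unspliced`
#' @export
count_matrix <- function(groups, barcodes = NULL, genes = NULL) {
  groups <- as.data.table(groups)
  if (is.null(barcodes)) barcodes <- sort(unique(groups$barcode))
  if (is.null(genes)) genes <- sort(unique(groups$gene_id))
  mk <- function(sub) {
    Matrix::sparseMatrix(
      i = match(sub$gene_id, genes),
      j = match(sub$barcode, barcodes),
      x = sub$N,
      dims = c(length(genes), length(barcodes)),
      dimnames = list(genes, barcodes)
    )
  }
  spl <- groups[splice == "spliced", .N, by = .(gene_id, barcode)]
  uns <- groups[splice == "unspliced", .N, by = .(gene_id, barcode)]
  list(spliced = mk(spl), unspliced = mk(uns))
}
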