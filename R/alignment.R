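# Alignment merging, score filtering, splice-overhang trimming and the
# six-type / read-level annotation schema.

ALIGNMENT_TYPES <- c("unmapped", "antisense", "exonic", "intronic",
                     "intergenic", "ambiguous")
READ_ANNOTATIONS <- c("multi_mapped", "antisense", "ambiguous", "exonic",
                      "intronic", "intergenic", "unmapped")

#' Trim terminal aligned blocks that overhang annotated splice junctions
#'
#' Mis-spliced reads whose terminal aligned block extends a few bases past an
#' annotated splice site are a common source of false-positive mismatches.
#' When a terminal block crosses an annotated junction boundary by at most
#' `max_overhang` bases, the overhang is converted to a soft clip; both read
#' ends are checked. Longer overhangs are left untouched.
#'
#' @param aln data.table with `aln_id`, `contig`, `pos` (0-based), `cigar`,
#'   `strand`
#' @param index a `ref_index` (supplies the junction set)
#' @param max_overhang maximum overhang, in bases, that is trimmed (default 5)
#' @return the alignment table with `pos`/`cigar` adjusted
#' @export
trim_splice_overhang <- function(aln, index, max_overhang = 5L) {
  aln <- copy(as.data.table(aln))
  jx <- index$junctions
  if (!nrow(jx) || !nrow(aln)) return(aln)
  segs <- aln_segments(aln$pos, aln$cigar)
  first_seg <- segs[, .SD[1L], by = aln_id]
  last_seg <- segs[, .SD[.N], by = aln_id]

  for (i in seq_len(nrow(aln))) {
    ct <- aln$contig[i]
    jc <- jx[contig == ct]
    if (!nrow(jc)) next
    ops <- GenomicAlignments::explodeCigarOps(aln$cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar[i])[[1]]

    # 3' (right) end: last block [s, e); a donor d with s < d < e and
    # e - d <= max_overhang means the block runs into the intron at d
    ls <- last_seg[aln_id == i]
    cand3 <- jc$donor[jc$donor > ls$ref_start & jc$donor < ls$ref_end &
                        (ls$ref_end - jc$donor) <= max_overhang]
    if (length(cand3)) {
      clip <- ls$ref_end - max(cand3)
      n <- length(ops)
      stopifnot(ops[n] == "M", lens[n] > clip)
      lens[n] <- lens[n] - clip
      if (n >= 1L) { ops <- c(ops, "S"); lens <- c(lens, clip) }
    }
    # 5' (left) end: first block [s, e); an acceptor a with s < a < e and
    # a - s <= max_overhang means the block starts inside the upstream intron
    fs <- first_seg[aln_id == i]
    cand5 <- jc$acceptor[jc$acceptor > fs$ref_start & jc$acceptor < fs$ref_end &
                           (jc$acceptor - fs$ref_start) <= max_overhang]
    if (length(cand5)) {
      clip <- min(cand5) - fs$ref_start
      k <- if (ops[1] == "S") 2L else 1L
      stopifnot(ops[k] == "M", lens[k] > clip)
      lens[k] <- lens[k] - clip
      if (k == 1L) { ops <- c("S", ops); lens <- c(clip, lens) }
      else lens[1L] <- lens[1L] + clip
      aln$pos[i] <- aln$pos[i] + clip
    }
    if (length(cand3) || length(cand5)) {
      aln$cigar[i] <- paste0(lens, ops, collapse = "")
    }
  }
  aln
}

#' Score-filter a read's candidate alignments
#'
#' Drops candidates below the absolute score cutoff, then retains every
#' candidate within `score_window` of the best remaining score. Intergenic
#' candidates participate fully, so a genic and an intergenic alignment with
#' equal scores both survive (and the read later becomes multi-mapped).
#'
#' @param cand data.table of candidate alignments with a `score` column;
#'   duplicates by (`contig`, `pos`, `cigar`, `strand`) are removed first
#' @param min_score absolute minimum aligner score (default 45)
#' @param score_window retain scores `>= max(score) - score_window` (default 3)
#' @return the retained subset (possibly empty; the read is then unmapped)
#' @export
merge_and_filter <- function(cand, min_score = 45L, score_window = 3L) {
  cand <- as.data.table(cand)
  if (!nrow(cand)) return(cand)
  cand <- unique(cand, by = intersect(c("contig", "pos", "cigar", "strand"),
                                      names(cand)))
  cand <- cand[score >= min_score]
  if (!nrow(cand)) return(cand)
  cand[score >= max(score) - score_window]
}

#' Classify one alignment by its gene overlaps
#'
#' Transcriptome-sourced alignments are exonic by construction. Genomic
#' alignments are exonic with more than `min_exon_bp` aligned bases in the
#' exons of a single sense-strand gene; intronic with more than `min_intron_bp`
#' intron bases and no exon overlap in a single sense-strand gene; ambiguous
#' when overlapping more than one sense-strand gene; antisense when their only
#' gene overlaps are on the opposite strand; intergenic otherwise.
#'
#' @param source `"genome"` or `"transcriptome"`
#' @param overlaps the rows of [annotate_overlap()] for this alignment
#'   (possibly empty)
#' @param min_exon_bp,min_intron_bp overlap thresholds (defaults 25 and 5,
#'   both strict)
#' @return list with `type` (an alignment type) and `gene_id` (NA unless the
#'   type assigns a unique gene)
#' @export
classify_alignment <- function(source, overlaps,
                               min_exon_bp = 25L, min_intron_bp = 5L) {
  ov <- as.data.table(overlaps)
  if (source == "transcriptome") {
    gid <- if (nrow(ov)) ov$gene_id[which.max(ov$exon_bp)] else NA_character_
    return(list(type = "exonic", gene_id = gid))
  }
  if (!nrow(ov)) return(list(type = "intergenic", gene_id = NA_character_))
  sense <- ov[antisense == FALSE]
  if (!nrow(sense)) return(list(type = "antisense", gene_id = NA_character_))
  if (nrow(sense) > 1L) return(list(type = "ambiguous", gene_id = NA_character_))
  if (sense$exon_bp > min_exon_bp) {
    return(list(type = "exonic", gene_id = sense$gene_id))
  }
  if (sense$exon_bp == 0L && sense$intron_bp > min_intron_bp) {
    return(list(type = "intronic", gene_id = sense$gene_id))
  }
  list(type = "intergenic", gene_id = NA_character_)
}

# cluster retained alignments of one read into distinct genomic locations:
# same location = same contig and >=50% reciprocal span overlap. Returns an
# integer cluster id per alignment.
.location_clusters <- function(contig, start, end) {
  n <- length(contig)
  cl <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (contig[i] != contig[j]) next
      ov <- min(end[i], end[j]) - max(start[i], start[j])
      if (ov <= 0) next
      if (ov >= 0.5 * (end[i] - start[i]) && ov >= 0.5 * (end[j] - start[j])) {
        cl[cl == cl[j]] <- cl[i]
      }
    }
  }
  match(cl, unique(cl))
}

#' Annotate a read from its retained, classified alignments
#'
#' Applies the read-level schema: multi-mapped when the alignments fall in more
#' than one distinct genomic location (two alignments share a location when
#' they are on the same contig and their reference spans overlap reciprocally
#' by at least 50%); antisense when all alignments are antisense; ambiguous
#' when all are ambiguous or the read has both an intronic and an exonic
#' alignment within the same gene; exonic/intronic when the alignments agree
#' on a single gene. Only exonic and intronic reads are countable downstream.
#'
#' @param types character vector of alignment types (from
#'   [classify_alignment()])
#' @param gene_ids character vector of assigned genes (NA allowed)
#' @param contig,start,end per-alignment reference span (0-based half-open)
#' @return list with `annotation` and `gene_id`
#' @export
annotate_read <- function(types, gene_ids, contig, start, end) {
  n <- length(types)
  if (n == 0L) return(list(annotation = "unmapped", gene_id = NA_character_))
  cl <- .location_clusters(contig, start, end)
  if (length(unique(cl)) > 1L) {
    return(list(annotation = "multi_mapped", gene_id = NA_character_))
  }
  if (all(types == "antisense")) {
    return(list(annotation = "antisense", gene_id = NA_character_))
  }
  if (all(types == "ambiguous")) {
    return(list(annotation = "ambiguous", gene_id = NA_character_))
  }
  genes <- unique(gene_ids[!is.na(gene_ids)])
  if (length(genes) == 1L) {
    has_ex <- any(types == "exonic" & gene_ids == genes)
    has_in <- any(types == "intronic" & gene_ids == genes)
    if (has_ex && has_in) {
      return(list(annotation = "ambiguous", gene_id = NA_character_))
    }
    if (has_ex) return(list(annotation = "exonic", gene_id = genes))
    if (has_in) return(list(annotation = "intronic", gene_id = genes))
  }
  if (length(genes) > 1L) {
    # same location but conflicting gene assignment: ambiguous
    return(list(annotation = "ambiguous", gene_id = NA_character_))
  }
  list(annotation = "intergenic", gene_id = NA_character_)
}

#' Classify and annotate a whole alignment table
#'
#' Vectorised driver for gold or externally aligned reads: computes gene
#' overlaps, classifies each alignment, and reduces each read's retained
#' alignments to a single read annotation. Input alignments are assumed to
#' have passed score filtering ([merge_and_filter()]) per read.
#'
#' @param aln data.table with `read_id`, `contig`, `pos`, `cigar`, `strand`,
#'   `source` (`"genome"`/`"transcriptome"`)
#' @param index a `ref_index`
#' @param min_exon_bp,min_intron_bp see [classify_alignment()]
#' @return data.table keyed by `read_id` with `annotation` and `gene_id`
#' @export
annotate_reads <- function(aln, index, min_exon_bp = 25L, min_intron_bp = 5L) {
  aln <- as.data.table(aln)
  aln[, aln_id := .I]
  ov <- annotate_overlap(aln[, .(aln_id, contig, pos, cigar, strand)], index)

  # vectorised per-alignment classification
  sense <- ov[antisense == FALSE]
  n_sense <- sense[, .N, by = aln_id]
  one_sense <- sense[aln_id %in% n_sense[N == 1L, aln_id]]
  any_ov <- unique(ov$aln_id)

  aln[, type := "intergenic"]
  aln[!aln_id %in% any_ov, type := "intergenic"]
  aln[aln_id %in% setdiff(any_ov, sense$aln_id), type := "antisense"]
  aln[aln_id %in% n_sense[N > 1L, aln_id], type := "ambiguous"]
  aln[, gene_id := NA_character_]
  if (nrow(one_sense)) {
    ex <- one_sense[exon_bp > min_exon_bp]
    io <- one_sense[exon_bp == 0L & intron_bp > min_intron_bp]
    aln[ex, on = "aln_id", `:=`(type = "exonic", gene_id = i.gene_id)]
    aln[io, on = "aln_id", `:=`(type = "intronic", gene_id = i.gene_id)]
  }
  aln[source == "transcriptome", type := "exonic"]

  spans <- aln_segments(aln$pos, aln$cigar)[, .(span_start = min(ref_start),
                                                span_end = max(ref_end)),
                                            by = aln_id]
  aln[spans, on = "aln_id", `:=`(span_start = i.span_start,
                                 span_end = i.span_end)]

  # fast path: reads with a single retained alignment map 1:1 to annotations
  aln[, n_aln := .N, by = read_id]
  singles <- aln[n_aln == 1L, .(read_id, annotation = type, gene_id)]
  multi <- aln[n_aln > 1L]
  res <- singles
  if (nrow(multi)) {
    res_multi <- multi[, {
      r <- annotate_read(type, gene_id, contig, span_start, span_end)
      .(annotation = r$annotation, gene_id = r$gene_id)
    }, by = read_id]
    res <- rbindlist(list(singles, res_multi))
  }
  setkey(res, read_id)
  res[]
}
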