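#' Build a filtered full-length transcript reference index
#'
#' Parses Ensembl-dialect GTF gene models and a genome FASTA into the interval
#' structures used by every downstream step: per-gene unioned exons, derived
#' introns, per-transcript exon chains for coordinate projection, and the set
#' of annotated splice junctions. Transcripts with an excluded biotype
#' (by default `retained_intron`, `nonsense_mediated_decay`, `non_stop_decay`)
#' or a spliced length below `min_tx_length` are removed before any structure
#' is derived, so excluded transcripts contribute neither exons nor junctions.
#'
#' @param gtf_file path to a GTF file with `gene_id`, `transcript_id` and
#'   `gene_biotype`/`transcript_biotype` attributes.
#' @param fasta_file path to the genome FASTA (an `.fai` index is not required;
#'   the sequences are held in memory).
#' @param excluded_biotypes character vector of transcript biotypes to drop.
#' @param min_tx_length minimum spliced transcript length in bases; transcripts
#'   strictly shorter are dropped.
#' @param tx_fasta_out optional path; when given, the spliced sequences of the
#'   retained transcripts are written as FASTA for an external aligner.
#' @return an object of class `ref_index`: a list with elements `genes`,
#'   `transcripts`, `exon_chains`, `gene_exons`, `gene_introns`, `junctions`
#'   (all data.tables, 0-based half-open coordinates), `genome`
#'   (a [Biostrings::DNAStringSet]) and prebuilt `GRanges` lookups.
#' @export
build_index <- function(gtf_file, fasta_file,
                        excluded_biotypes = c("retained_intron",
                                              "nonsense_mediated_decay",
                                              "non_stop_decay"),
                        min_tx_length = 100L,
                        tx_fasta_out = NULL) {
  genome <- Biostrings::readDNAStringSet(fasta_file)
  names(genome) <- sub("\\s.*$", "", names(genome))

  gr <- rtracklayer::import(gtf_file, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("GTF contains no exon records")
  biotype <- if (!is.null(ex$transcript_biotype)) ex$transcript_biotype else ex$gene_biotype
  if (is.null(biotype)) biotype <- rep("protein_coding", length(ex))
  exons <- data.table(
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id,
    contig = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = BiocGenerics::start(ex) - 1L,
    end = BiocGenerics::end(ex),
    biotype = biotype
  )

  bad_contig <- setdiff(unique(exons$contig), names(genome))
  if (length(bad_contig)) {
    stop("transcript references unknown contig(s): ", paste(bad_contig, collapse = ", "))
  }
  clen <- Biostrings::width(genome)[match(exons$contig, names(genome))]
  if (any(exons$start < 0L | exons$end > clen)) {
    stop("exon outside contig bounds")
  }

  transcripts <- exons[, .(
    gene_id = gene_id[1], contig = contig[1], strand = strand[1],
    length = sum(end - start), biotype = biotype[1]
  ), by = transcript_id]
  keep_tx <- transcripts[!(biotype %in% excluded_biotypes) & length >= min_tx_length,
                         transcript_id]
  transcripts <- transcripts[transcript_id %in% keep_tx]
  exons <- exons[transcript_id %in% keep_tx]
  if (!nrow(exons)) stop("no transcripts retained after filtering")

  # exon chain ordered 5'->3' in transcript orientation
  setorder(exons, transcript_id, start)
  exon_chains <- exons[, {
    o <- if (strand[1] == "+") order(start) else order(-start)
    .(rank = seq_along(o), start = start[o], end = end[o],
      gene_id = gene_id[1], contig = contig[1], strand = strand[1])
  }, by = transcript_id]

  # per-gene union of exons over retained transcripts; introns are the gaps
  gene_exons <- exons[, {
    ir <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
    .(contig = contig[1], strand = strand[1],
      start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
  }, by = gene_id]
  genes <- gene_exons[, .(
    contig = contig[1], strand = strand[1],
    start = min(start), end = max(end)
  ), by = gene_id]
  genes[, biotype := transcripts$biotype[match(gene_id, transcripts$gene_id)]]
  gene_introns <- gene_exons[, {
    if (.N > 1L) .(contig = contig[1], strand = strand[1],
                   start = end[-.N], end = start[-1L])
    else .(contig = character(), strand = character(),
           start = integer(), end = integer())
  }, by = gene_id]

  # junctions from retained transcripts: (contig, donor, acceptor) with the
  # intron as [donor, acceptor) in genomic coordinates
  jx <- exons[, {
    o <- order(start)
    if (.N > 1L) .(contig = contig[1],
                   donor = end[o][-.N], acceptor = start[o][-1L])
    else .(contig = character(), donor = integer(), acceptor = integer())
  }, by = transcript_id]
  junctions <- unique(jx[, .(contig, donor, acceptor)])

  idx <- structure(list(
    genes = genes,
    transcripts = transcripts,
    exon_chains = exon_chains,
    gene_exons = gene_exons,
    gene_introns = gene_introns,
    junctions = junctions,
    genome = genome,
    excluded_biotypes = excluded_biotypes,
    min_tx_length = min_tx_length
  ), class = "ref_index")
  idx$exons_gr <- .interval_gr(gene_exons)
  idx$introns_gr <- .interval_gr(gene_introns)

  if (!is.null(tx_fasta_out)) {
    writeXStringSet_tx(idx, tx_fasta_out)
  }
  idx
}

.interval_gr <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = dt$contig,
    ranges = IRanges::IRanges(dt$start + 1L, dt$end),
    strand = dt$strand,
    gene_id = dt$gene_id
  )
}

#' @export
print.ref_index <- function(x, ...) {
  cat("ref_index:", nrow(x$genes), "genes,", nrow(x$transcripts), "transcripts,",
      nrow(x$junctions), "junctions,", length(x$genome), "contigs\n")
  invisible(x)
}

#' Spliced transcript sequence
#'
#' @param index a `ref_index`
#' @param transcript_id transcript identifier
#' @return character scalar, the 5'->3' mRNA sequence
#' @export
transcript_seq <- function(index, transcript_id) {
  tid <- transcript_id
  ch <- index$exon_chains[transcript_id == tid][order(rank)]
  if (!nrow(ch)) stop("unknown transcript: ", transcript_id)
  segs <- ref_chunks(index$genome, ch$contig, ch$start, ch$end)
  if (ch$strand[1] == "-") segs <- revcomp(segs)
  # chain is already 5'->3': for minus transcripts ranks run along descending
  # genomic coordinates, so reverse-complemented segments concatenate directly
  paste(segs, collapse = "")
}

writeXStringSet_tx <- function(index, path) {
  ids <- index$transcripts$transcript_id
  seqs <- vapply(ids, function(tx) transcript_seq(index, tx), character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(seqs, ids)), path)
}

#' Project a transcript-space alignment to genomic coordinates
#'
#' Maps an alignment expressed in transcript coordinates onto the genome using
#' the transcript's exon chain. Match (and deletion) operations are split at
#' exon boundaries and reference-skip (`N`) operations are inserted across
#' introns; insertions and soft clips pass through unchanged. The genomic
#' strand is the transcript strand composed with the alignment orientation.
#'
#' @param index a `ref_index`
#' @param transcript_id the transcript the alignment is against
#' @param start 0-based alignment start in transcript coordinates
#' @param cigar alignment cigar in transcript space (`M`, `I`, `D`, `S`)
#' @param aln_strand orientation of the query on the transcript (`"+"`/`"-"`)
#' @return list with `contig`, `pos` (0-based), `cigar` (genomic, ascending
#'   coordinates) and `strand`
#' @export
project_to_genome <- function(index, transcript_id, start, cigar, aln_strand = "+") {
  tid <- transcript_id
  ch <- index$exon_chains[transcript_id == tid][order(rank)]
  if (!nrow(ch)) stop("zero-length exon chain for transcript ", transcript_id)
  tx_strand <- ch$strand[1]
  widths <- ch$end - ch$start
  cum <- c(0L, cumsum(widths))
  tx_len <- cum[length(cum)]

  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref_len <- sum(lens[ops %in% c("M", "D", "N")])
  if (start < 0L || start + ref_len > tx_len) {
    stop("alignment exceeds transcript bounds")
  }

  # walk ops in transcript orientation, splitting ref-consuming ops at exon
  # boundaries; each piece carries its genomic start for ref-consuming ops
  pieces <- list()
  t <- as.integer(start)
  for (i in seq_along(ops)) {
    op <- ops[i]; w <- lens[i]
    if (op %in% c("I", "S")) {
      pieces[[length(pieces) + 1L]] <- list(op = op, len = w, g = NA_integer_)
      next
    }
    if (!op %in% c("M", "D")) stop("unsupported cigar op in transcript space: ", op)
    remaining <- w
    while (remaining > 0L) {
      k <- findInterval(t, cum, rightmost.closed = FALSE)  # exon index (1-based)
      take <- min(remaining, cum[k + 1L] - t)
      g <- if (tx_strand == "+") ch$start[k] + (t - cum[k])
           else ch$end[k] - (t - cum[k]) - take
      pieces[[length(pieces) + 1L]] <- list(op = op, len = take, g = g)
      t <- t + take
      remaining <- remaining - take
    }
  }
  if (tx_strand == "-") pieces <- rev(pieces)

  # assemble genomic cigar in ascending coordinates, inserting N across gaps
  parts <- character(0)
  gpos <- NA_integer_
  cur_end <- NA_integer_
  for (p in pieces) {
    if (p$op %in% c("I", "S")) {
      parts <- c(parts, paste0(p$len, p$op))
      next
    }
    if (is.na(gpos)) {
      gpos <- p$g
    } else if (p$g > cur_end) {
      parts <- c(parts, paste0(p$g - cur_end, "N"))
    }
    parts <- c(parts, paste0(p$len, p$op))
    cur_end <- p$g + p$len
  }
  # merge adjacent identical ops (e.g. M pieces abutting within an exon)
  cig <- .merge_cigar(paste(parts, collapse = ""))
  g_strand <- if (aln_strand == "+") tx_strand else setdiff(c("+", "-"), tx_strand)
  list(contig = ch$contig[1], pos = gpos, cigar = cig, strand = g_strand)
}

.merge_cigar <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  keep_op <- character(0); keep_len <- integer(0)
  for (i in seq_along(ops)) {
    if (length(keep_op) && keep_op[length(keep_op)] == ops[i]) {
      keep_len[length(keep_len)] <- keep_len[length(keep_len)] + lens[i]
    } else {
      keep_op <- c(keep_op, ops[i]); keep_len <- c(keep_len, lens[i])
    }
  }
  paste0(keep_len, keep_op, collapse = "")
}

#' Per-gene exon/intron overlap of genomic alignments
#'
#' Measures, for each alignment and each gene it touches, how many aligned
#' reference bases fall in the gene's unioned exons and derived introns, and
#' whether the alignment is on the gene's opposite strand.
#'
#' @param aln data.table with columns `aln_id`, `contig`, `pos` (0-based),
#'   `cigar`, `strand`
#' @param index a `ref_index`
#' @return data.table with columns `aln_id`, `gene_id`, `exon_bp`, `intron_bp`,
#'   `antisense`; alignments with no gene overlap are absent.
#' @export
annotate_overlap <- function(aln, index) {
  aln <- as.data.table(aln)
  if (!nrow(aln)) {
    return(data.table(aln_id = integer(), gene_id = character(),
                      exon_bp = integer(), intron_bp = integer(),
                      antisense = logical()))
  }
  segs <- aln_segments(aln$pos, aln$cigar)
  segs[, contig := aln$contig[aln_id]]
  gr <- GenomicRanges::GRanges(segs$contig,
                               IRanges::IRanges(segs$ref_start + 1L, segs$ref_end))

  ov_count <- function(target_gr) {
    hits <- GenomicRanges::findOverlaps(gr, target_gr, ignore.strand = TRUE)
    if (!length(hits)) {
      return(data.table(aln_id = integer(), gene_id = character(), bp = integer()))
    }
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    w <- BiocGenerics::width(IRanges::pintersect(
      IRanges::ranges(gr)[q], IRanges::ranges(target_gr)[s]))
    data.table(aln_id = segs$aln_id[q], gene_id = target_gr$gene_id[s], bp = w)[
      , .(bp = sum(bp)), by = .(aln_id, gene_id)]
  }

  exo <- ov_count(index$exons_gr)
  intr <- ov_count(index$introns_gr)
  out <- merge(exo, intr, by = c("aln_id", "gene_id"), all = TRUE,
               suffixes = c("_exon", "_intron"))
  setnames(out, c("bp_exon", "bp_intron"), c("exon_bp", "intron_bp"))
  out[is.na(exon_bp), exon_bp := 0L]
  out[is.na(intron_bp), intron_bp := 0L]
  gstrand <- index$genes$strand[match(out$gene_id, index$genes$gene_id)]
  out[, antisense := aln$strand[aln_id] != gstrand]
  setorder(out, aln_id, gene_id)
  out[]
}
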