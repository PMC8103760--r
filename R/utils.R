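# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; conversion to 1-based happens only at the
# IRanges/GRanges and VCF boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @importFrom data.table data.table as.data.table setDT setnames setorder
#'   setkey rbindlist fifelse := .N .SD .GRP .I
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", "..keep", "aln_id", "alt", "alt_bases", "annotation", "barcode", "base",
  "biotype", "block_i", "cand", "cigar", "contig", "count", "depth", "end",
  "end_dist", "exon_bp", "gene_id", "group_id", "i.end", "i.start", "intron_bp",
  "mol_id", "n_alt", "n_reads", "pos", "q_start", "qual", "read_id", "ref",
  "ref_end", "ref_start", "score", "seg_id", "seq", "splice", "start", "strand",
  "transcript_id", "tx_pos", "umi", "value", "width"
))

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# All sequences at Hamming distance exactly 1 from each input string.
# Returns data.table(orig, neighbor).
hamming1_neighbors <- function(seqs) {
  if (!length(seqs)) return(data.table(orig = character(), neighbor = character()))
  L <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  out <- vector("list", L * 3L)
  k <- 0L
  for (i in seq_len(L)) {
    for (b in BASES) {
      keep <- mat[, i] != b
      if (!any(keep)) next
      m2 <- mat[keep, , drop = FALSE]
      m2[, i] <- b
      k <- k + 1L
      out[[k]] <- data.table(
        orig = seqs[keep],
        neighbor = apply_paste_rows(m2)
      )
    }
  }
  rbindlist(out[seq_len(k)])
}

apply_paste_rows <- function(m) {
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# phred+33 string <-> integer qualities
qual_to_int <- function(q) {
  lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}

int_to_qual <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

# Per-M-segment decomposition of alignments. `pos` is the 0-based leftmost
# reference coordinate. Returns a data.table with one row per aligned (M)
# segment: aln_id, ref_start/ref_end (0-based half-open), q_start (0-based
# offset into the stored, reference-oriented sequence), width.
aln_segments <- function(pos, cigar) {
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = pos + 1L, ops = "M")
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = "M")
  n_per <- S4Vectors::elementNROWS(rr)
  rru <- unlist(rr, use.names = FALSE)
  qru <- unlist(qr, use.names = FALSE)
  data.table(
    aln_id = rep(seq_along(cigar), n_per),
    ref_start = BiocGenerics::start(rru) - 1L,
    ref_end = BiocGenerics::end(rru),
    q_start = BiocGenerics::start(qru) - 1L,
    width = BiocGenerics::width(rru)
  )
}

# Reference-skip (N) intervals of alignments, 0-based half-open.
aln_skips <- function(pos, cigar) {
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = pos + 1L, ops = "N")
  n_per <- S4Vectors::elementNROWS(rr)
  rru <- unlist(rr, use.names = FALSE)
  data.table(
    aln_id = rep(seq_along(cigar), n_per),
    ref_start = BiocGenerics::start(rru) - 1L,
    ref_end = BiocGenerics::end(rru)
  )
}

# Build a cigar string from a matrix of 0-based half-open match blocks
# (gaps between blocks become N ops), plus optional soft clips.
blocks_to_cigar <- function(blocks, clip5 = 0L, clip3 = 0L) {
  w <- blocks[, 2] - blocks[, 1]
  ops <- paste0(w, "M")
  if (nrow(blocks) > 1L) {
    gaps <- blocks[-1L, 1] - blocks[-nrow(blocks), 2]
    ops <- c(rbind(ops[-length(ops)], paste0(gaps, "N")), ops[length(ops)])
  }
  s <- paste(ops, collapse = "")
  if (clip5 > 0L) s <- paste0(clip5, "S", s)
  if (clip3 > 0L) s <- paste0(s, clip3, "S")
  s
}

# Extract reference sequence for 0-based half-open intervals on one contig.
ref_chunk <- function(genome, contig, start0, end0) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  as.character(Biostrings::subseq(genome[[contig]], start0 + 1L, end0))
}

# Vectorised reference extraction: one string per (contig, start0, end0) row.
ref_chunks <- function(genome, contig, start0, end0) {
  out <- character(length(contig))
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    v <- Biostrings::Views(genome[[ct]], start = start0[idx] + 1L, end = end0[idx])
    out[idx] <- as.character(v)
  }
  out
}

# distance from each position to its nearest value in `ends` (both integer)
dist_to_nearest <- function(pos, ends) {
  if (!length(ends)) return(rep(Inf, length(pos)))
  ends <- sort(ends)
  i <- findInterval(pos, ends)
  lo <- ifelse(i >= 1L, abs(pos - ends[pmax(i, 1L)]), Inf)
  hi <- ifelse(i < length(ends), abs(ends[pmin(i + 1L, length(ends))] - pos), Inf)
  pmin(lo, hi)
}

# consistent integer RNG seeding: derive a stream seed below 2^31
derive_seed <- function(seed, offset = 0L) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}
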