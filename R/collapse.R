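# Consensus collapsing of UMI groups into molecules. Works column-wise over
# the union of aligned reference positions of a group's reads; per-column
# majority at >= consensus_fraction, ambiguous (N, quality 2) otherwise.

#' Consensus parameters for molecule collapsing
#'
#' @param consensus_fraction minimum fraction of reads that must agree for a
#'   consensus base (default 0.60, compared with `>=`)
#' @param indel_fraction minimum fraction of overlapping reads that must carry
#'   an identical indel for it to be kept (default 0.60)
#' @return list of class `consensus_params`
#' @export
consensus_params <- function(consensus_fraction = 0.60, indel_fraction = 0.60) {
  stopifnot(consensus_fraction > 0.5, consensus_fraction <= 1,
            indel_fraction > 0.5, indel_fraction <= 1)
  structure(list(consensus_fraction = consensus_fraction,
                 indel_fraction = indel_fraction), class = "consensus_params")
}

#' Is a UMI group linear (collapsible)?
#'
#' A group can be collapsed when its reads lie on one contig and strand, carry
#' no insertions or deletions, and agree on reference-skip (splice junction)
#' structure: no read may skip a reference position that another member read
#' aligns to. Non-linear groups are passed through uncollapsed.
#'
#' @param contig,strand,pos,cigar member-read alignment fields
#' @return logical scalar
#' @export
is_linear_group <- function(contig, strand, pos, cigar) {
  if (length(unique(contig)) > 1L || length(unique(strand)) > 1L) return(FALSE)
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  if (any(vapply(ops, function(o) any(o %in% c("I", "D")), logical(1)))) {
    return(FALSE)
  }
  sk <- aln_skips(pos, cigar)
  if (!nrow(sk)) return(TRUE)
  segs <- aln_segments(pos, cigar)
  cov <- IRanges::reduce(IRanges::IRanges(segs$ref_start + 1L, segs$ref_end))
  skr <- IRanges::IRanges(sk$ref_start + 1L, sk$ref_end)
  !any(IRanges::overlapsAny(skr, cov))
}

#' Column-wise consensus base
#'
#' If the modal base reaches `consensus_fraction` of the column it wins with a
#' quality equal to the maximum base quality among its supporting reads;
#' otherwise the column is ambiguous: base `N` with quality 2.
#'
#' @param bases character vector of observed bases at one position
#' @param quals integer base qualities
#' @param consensus_fraction agreement threshold (default 0.60)
#' @return list with `base` and `qual`
#' @export
consensus_base <- function(bases, quals, consensus_fraction = 0.60) {
  tab <- table(bases)
  m <- max(tab)
  if (m / length(bases) >= consensus_fraction && sum(tab == m) == 1L) {
    b <- names(tab)[which.max(tab)]
    list(base = b, qual = max(quals[bases == b]))
  } else {
    list(base = "N", qual = 2L)
  }
}

#' Consensus decision for an indel locus
#'
#' An indel is retained only when at least `indel_fraction` of the reads
#' overlapping its locus carry the exact same indel sequence; otherwise the
#' reference allele is emitted.
#'
#' @param indels character vector of indel descriptors carried by reads at the
#'   locus (e.g. `"I:AG"` or `"D:3"`), `NA` for overlapping reads without one
#' @param indel_fraction agreement threshold (default 0.60)
#' @return the winning indel descriptor, or `NA_character_` when rejected
#' @export
consensus_indel <- function(indels, indel_fraction = 0.60) {
  n <- length(indels)
  obs <- indels[!is.na(indels)]
  if (!length(obs)) return(NA_character_)
  tab <- table(obs)
  m <- max(tab)
  if (m / n >= indel_fraction && sum(tab == m) == 1L) names(tab)[which.max(tab)]
  else NA_character_
}

#' Collapse UMI groups into consensus molecules
#'
#' Merges each linear UMI group's reads into one consensus record covering the
#' union of their aligned reference positions, with per-base consensus base,
#' quality and depth, total mapped bases, and the set of internal read-end
#' positions (reference positions where a member read starts or ends strictly
#' inside the molecule span - these later count as read ends for the SNV
#' end-distance filter). Non-linear groups are passed through as their original
#' reads with `collapsed = FALSE`.
#'
#' @param reads data.table of countable reads: `read_id`, `contig`, `pos`,
#'   `cigar`, `strand`, `seq`, `qual` (reference-oriented, phred+33)
#' @param groups,read_groups from [build_umi_groups()]
#' @param params a [consensus_params()] object
#' @return data.table of molecules: `mol_id`, `group_id`, `barcode`, `umi`,
#'   `gene_id`, `splice`, `contig`, `strand`, `pos`, `cigar`, `seq`, `qual`,
#'   `depth` (list), `mapped_bases`, `internal_ends` (list),
#'   `n_reads`, `n_pcr_duplicates`, `n_unique_positions`, `collapsed`
#' @export
collapse_molecules <- function(reads, groups, read_groups,
                               params = consensus_params()) {
  reads <- as.data.table(reads)
  groups <- as.data.table(groups)
  rg <- merge(as.data.table(read_groups), reads, by = "read_id")
  setorder(rg, group_id, read_id)

  # linearity per group, vectorised: groups on one contig/strand whose reads
  # carry no indels and either no reference skips or skips that never overlap
  # another member's aligned segments are linear
  rg[, simple := !grepl("[ID]", cigar)]
  rg[, has_skip := grepl("N", cigar)]
  gstat <- rg[, .(
    n = .N,
    one_pos = data.table::uniqueN(paste(pos, cigar)) == 1L,
    one_seq = data.table::uniqueN(seq) == 1L,
    all_simple = all(simple),
    any_skip = any(has_skip),
    one_cs = data.table::uniqueN(paste(contig, strand)) == 1L
  ), by = group_id]
  # single-read groups always collapse to themselves (identity)
  gstat[, lin := (all_simple | n == 1L) & one_cs]
  chk_ids <- gstat[lin == TRUE & any_skip & !one_pos, group_id]
  if (length(chk_ids)) {
    sub <- rg[group_id %in% chk_ids]
    segs_c <- aln_segments(sub$pos, sub$cigar)
    segs_c[, gid := sub$group_id[aln_id]]
    skips_c <- aln_skips(sub$pos, sub$cigar)
    if (nrow(skips_c)) {
      skips_c[, gid := sub$group_id[aln_id]]
      # closed-interval representation of half-open blocks for foverlaps
      segs_c[, `:=`(start = ref_start, end = ref_end - 1L)]
      skips_c[, `:=`(start = ref_start, end = ref_end - 1L)]
      setkey(segs_c, gid, start, end)
      conf <- data.table::foverlaps(skips_c, segs_c, type = "any",
                                    nomatch = NULL)
      bad <- unique(conf$gid)
      if (length(bad)) gstat[group_id %in% bad, lin := FALSE]
    }
  }
  rg[gstat, on = "group_id", `:=`(lin = i.lin, n = i.n, one_pos = i.one_pos,
                                  one_seq = i.one_seq)]

  single <- rg[lin == TRUE & n == 1L]
  stack <- rg[lin == TRUE & n > 1L & one_pos & one_seq]
  multi <- rg[lin == TRUE & n > 1L & !(one_pos & one_seq)]
  passthru <- rg[lin == FALSE]

  out <- list()

  if (nrow(single)) {
    segs <- aln_segments(single$pos, single$cigar)
    sp <- segs[, .(span_start = min(ref_start), span_end = max(ref_end),
                   mapped = sum(ref_end - ref_start)), by = aln_id]
    out$single <- data.table(
      group_id = single$group_id,
      contig = single$contig, strand = single$strand,
      pos = single$pos, cigar = single$cigar,
      seq = single$seq, qual = single$qual,
      depth = lapply(sp$mapped, function(m) rep(1L, m)),
      mapped_bases = sp$mapped,
      internal_ends = rep(list(integer(0)), nrow(single)),
      collapsed = TRUE
    )
  }

  if (nrow(stack)) {
    # pure PCR stacks: identical layout and sequence; consensus is the common
    # read with per-base maximum quality and depth = number of copies
    st <- stack[, .(contig = contig[1L], strand = strand[1L], pos = pos[1L],
                    cigar = cigar[1L], seq = seq[1L],
                    qual = {
                      q <- lapply(qual, function(s) as.integer(charToRaw(s)))
                      rawToChar(as.raw(Reduce(pmax, q)))
                    },
                    nq = .N), by = group_id]
    segs <- aln_segments(st$pos, st$cigar)
    sp <- segs[, .(mapped = sum(ref_end - ref_start)), by = aln_id]
    st[, mapped_bases := sp$mapped[match(seq_len(.N), sp$aln_id)]]
    out$stack <- data.table(
      group_id = st$group_id, contig = st$contig, strand = st$strand,
      pos = st$pos, cigar = st$cigar, seq = st$seq, qual = st$qual,
      depth = mapply(function(m, n) rep(n, m), st$mapped_bases, st$nq,
                     SIMPLIFY = FALSE),
      mapped_bases = st$mapped_bases,
      internal_ends = rep(list(integer(0)), nrow(st)),
      collapsed = TRUE
    )
  }

  if (nrow(multi)) {
    out$multi <- .collapse_multi(multi, params)
  }

  if (nrow(passthru)) {
    segs <- aln_segments(passthru$pos, passthru$cigar)
    sp <- segs[, .(mapped = sum(ref_end - ref_start)), by = aln_id]
    out$pass <- data.table(
      group_id = passthru$group_id,
      contig = passthru$contig, strand = passthru$strand,
      pos = passthru$pos, cigar = passthru$cigar,
      seq = passthru$seq, qual = passthru$qual,
      depth = lapply(sp$mapped, function(m) rep(1L, m)),
      mapped_bases = sp$mapped,
      internal_ends = rep(list(integer(0)), nrow(passthru)),
      collapsed = FALSE
    )
  }

  mol <- rbindlist(out, use.names = TRUE)
  mol <- merge(mol, groups[, .(group_id, barcode, umi, gene_id, splice,
                               n_reads, n_pcr_duplicates, n_unique_positions)],
               by = "group_id")
  setorder(mol, contig, pos, group_id)
  mol[, mol_id := .I]
  mol[]
}

# column-wise consensus for groups with >1 read (vectorised over all groups)
.collapse_multi <- function(multi, params) {
  segs <- aln_segments(multi$pos, multi$cigar)
  w <- segs$width
  n_exp <- sum(w)
  row_of <- rep(segs$aln_id, w)           # row index into `multi`
  exp_pos <- rep(segs$ref_start, w) + sequence(w) - 1L
  qoff <- rep(segs$q_start, w) + sequence(w) - 1L

  seq_off <- cumsum(nchar(multi$seq)) - nchar(multi$seq)
  all_seq <- charToRaw(paste(multi$seq, collapse = ""))
  all_qual <- as.integer(charToRaw(paste(multi$qual, collapse = ""))) - 33L
  gidx <- seq_off[row_of] + qoff + 1L

  ex <- data.table(
    group_id = multi$group_id[row_of],
    pos = exp_pos,
    base = as.integer(all_seq[gidx]),
    qual = all_qual[gidx]
  )

  col <- ex[, .(cnt = .N, maxq = max(qual)), by = .(group_id, pos, base)]
  setorder(col, group_id, pos, -cnt, base)
  tot <- col[, .(n = sum(cnt), base = base[1L], cnt = cnt[1L],
                 nties = sum(cnt == cnt[1L]), maxq = maxq[1L]),
             by = .(group_id, pos)]
  ambiguous <- tot$cnt / tot$n < params$consensus_fraction | tot$nties > 1L
  tot[, cons_base := base]
  tot[ambiguous, cons_base := utf8ToInt("N")]
  tot[ambiguous, maxq := 2L]

  setorder(tot, group_id, pos)
  # block structure: runs of consecutive covered positions
  tot[, new_block := pos != data.table::shift(pos, fill = -10L) + 1L |
        group_id != data.table::shift(group_id, fill = -1L)]

  # per-read span boundaries feed internal read-end positions
  rspan <- segs[, .(rs = min(ref_start), re = max(ref_end)), by = aln_id]
  rspan[, group_id := multi$group_id[aln_id]]
  gspan <- rspan[, .(span_start = min(rs), span_end = max(re)), by = group_id]
  rspan <- merge(rspan, gspan, by = "group_id")
  iends <- rspan[, .(e = {
    v <- c(rs[rs > span_start], re[re < span_end] - 1L)
    sort(unique(v))
  }), by = group_id][, .(internal_ends = list(e)), by = group_id]

  mol <- tot[, {
    blocks <- cbind(pos[new_block], c(pos[which(new_block)[-1] - 1L], pos[.N]) + 1L)
    .(contig = NA_character_, strand = NA_character_,
      pos = pos[1L],
      cigar = blocks_to_cigar(blocks),
      seq = rawToChar(as.raw(cons_base)),
      qual = rawToChar(as.raw(maxq + 33L)),
      depth = list(n),
      mapped_bases = .N)
  }, by = group_id]

  gmeta <- multi[, .(contig = contig[1L], strand = strand[1L]), by = group_id]
  mol[gmeta, on = "group_id", `:=`(contig = i.contig, strand = i.strand)]
  mol <- merge(mol, iends, by = "group_id", all.x = TRUE)
  noie <- vapply(mol$internal_ends, is.null, logical(1))
  if (any(noie)) mol$internal_ends[noie] <- list(integer(0))
  mol[, collapsed := TRUE]
  mol[]
}
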