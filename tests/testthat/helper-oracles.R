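# Independent brute-force oracles used to validate the package's optimised
# implementations. These deliberately avoid the package's own code paths.

library(data.table)

# per-base transcript -> genome mapping by walking the exon chain one base at
# a time
oracle_tx_map <- function(index, transcript_id, tx_positions) {
  ch <- as.data.frame(index$exon_chains)
  ch <- ch[ch$transcript_id == transcript_id, ]
  ch <- ch[order(ch$rank), ]
  per_base <- integer(0)
  for (i in seq_len(nrow(ch))) {
    if (ch$strand[1] == "+") {
      per_base <- c(per_base, seq(ch$start[i], ch$end[i] - 1L))
    } else {
      per_base <- c(per_base, seq(ch$end[i] - 1L, ch$start[i]))
    }
  }
  per_base[tx_positions + 1L]
}

# genomic reference positions covered by an alignment, one base at a time
oracle_aln_positions <- function(pos, cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  out <- integer(0)
  cur <- pos
  for (i in seq_along(ops)) {
    if (ops[i] == "M") {
      out <- c(out, seq(cur, cur + lens[i] - 1L))
      cur <- cur + lens[i]
    } else if (ops[i] %in% c("D", "N")) {
      cur <- cur + lens[i]
    }
  }
  out
}

# DUST score by direct 3-mer tally
oracle_dust <- function(s) {
  L <- nchar(s)
  if (L < 4) return(0)
  k <- L - 2
  tri <- character(k)
  for (i in seq_len(k)) tri[i] <- substr(s, i, i + 2)
  ct <- table(tri)
  sum(ct * (ct - 1) / 2) / (k - 1)
}

# directional UMI collapse by explicit edge construction and recursive
# traversal in descending-count order
oracle_directional <- function(counts) {
  umis <- names(counts)
  n <- length(umis)
  if (n == 0) return(setNames(character(0), character(0)))
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && hd(umis[i], umis[j]) == 1 &&
          counts[i] >= 2 * counts[j] - 1) {
      edge[i, j] <- TRUE
    }
  }
  ord <- order(-counts, umis)
  root <- rep(NA_character_, n)
  visit <- function(i, r) {
    root[i] <<- r
    for (j in ord) {
      if (is.na(root[j]) && edge[i, j]) visit(j, r)
    }
  }
  for (i in ord) if (is.na(root[i])) visit(i, umis[i])
  setNames(root, umis)
}

# naive column-wise consensus over a UMI group: per reference position,
# majority base at >= 60% with max supporting quality, else N / 2
oracle_consensus <- function(reads) {
  # reads: data.table with pos, cigar, seq, qual (simple M/N cigars)
  cols <- list()
  for (i in seq_len(nrow(reads))) {
    gp <- oracle_aln_positions(reads$pos[i], reads$cigar[i])
    sq <- strsplit(reads$seq[i], "")[[1]]
    qq <- as.integer(charToRaw(reads$qual[i])) - 33L
    for (k in seq_along(gp)) {
      key <- as.character(gp[k])
      cols[[key]] <- rbind(cols[[key]],
                           data.frame(base = sq[k], qual = qq[k]))
    }
  }
  pos <- sort(as.integer(names(cols)))
  out <- data.frame(pos = pos, base = "", qual = 0L, depth = 0L)
  for (r in seq_along(pos)) {
    col <- cols[[as.character(pos[r])]]
    tab <- table(col$base)
    m <- max(tab)
    if (m / nrow(col) >= 0.60 && sum(tab == m) == 1) {
      b <- names(tab)[which.max(tab)]
      out$base[r] <- b
      out$qual[r] <- max(col$qual[col$base == b])
    } else {
      out$base[r] <- "N"
      out$qual[r] <- 2L
    }
    out$depth[r] <- nrow(col)
  }
  out
}

# naive pileup: walk every record base by base and tally per position
oracle_pileup <- function(records, genome, min_bq = 0L) {
  tal <- list()
  for (i in seq_len(nrow(records))) {
    gp <- oracle_aln_positions(records$pos[i], records$cigar[i])
    sq <- strsplit(records$seq[i], "")[[1]]
    qq <- as.integer(charToRaw(records$qual[i])) - 33L
    # sq indexes only M bases in order for M/N cigars
    for (k in seq_along(gp)) {
      if (qq[k] < min_bq || sq[k] == "N") next
      key <- paste(records$contig[i], gp[k])
      tal[[key]] <- rbind(tal[[key]], data.frame(
        base = sq[k], barcode = records$barcode[i],
        strand = records$strand[i]))
    }
  }
  tal
}

# simple deterministic quality string
qual_str <- function(q, n) strrep(rawToChar(as.raw(q + 33L)), n)
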