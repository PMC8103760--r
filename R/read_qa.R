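#' Quality-control parameters for tagged reads
#'
#' @param dust_threshold DUST low-complexity score above which a read is
#'   discarded; `NULL` disables the filter (the default).
#' @param min_fraction_after_polya minimum fraction of the original tag length
#'   that must remain after poly(A) trimming (default 0.5, i.e. at least half
#'   the read).
#' @param polya_min_run minimum length of a 3' A-run before any trimming.
#' @param polya_mismatch_per trimming tolerates one non-A base per this many
#'   bases of the run.
#' @return a list of class `qa_params`
#' @export
qa_params <- function(dust_threshold = NULL,
                      min_fraction_after_polya = 0.5,
                      polya_min_run = 6L,
                      polya_mismatch_per = 8L) {
  stopifnot(min_fraction_after_polya > 0, min_fraction_after_polya <= 1)
  structure(list(dust_threshold = dust_threshold,
                 min_fraction_after_polya = min_fraction_after_polya,
                 polya_min_run = as.integer(polya_min_run),
                 polya_mismatch_per = as.integer(polya_mismatch_per)),
            class = "qa_params")
}

#' Count exact whitelist matches of observed cell barcodes
#'
#' Only barcodes that match a whitelisted barcode exactly contribute; the
#' resulting counts drive mismatch correction (the candidate with the highest
#' exact-match count wins).
#'
#' @param barcodes character vector of observed raw barcodes
#' @param whitelist character vector of known barcodes (all the same length)
#' @return named integer vector over the whitelist entries that were observed
#' @export
count_barcodes <- function(barcodes, whitelist) {
  if (!length(whitelist)) stop("whitelist must be non-empty")
  hit <- barcodes[barcodes %in% whitelist]
  if (!length(hit)) return(setNames(integer(0), character(0)))
  tab <- table(hit)
  setNames(as.integer(tab), names(tab))
}

#' Correct cell barcodes against a whitelist
#'
#' An exact whitelist match is returned unchanged. Otherwise, if one or more
#' whitelisted barcodes lie at Hamming distance 1 from the observed barcode,
#' the one with the highest exact-match count (which must be at least 1) is
#' chosen; an exact tie in counts rejects the read. Barcodes containing
#' ambiguous bases, or with no whitelist neighbour, return `NA`.
#'
#' @param observed character vector of observed barcodes
#' @param whitelist character vector of known barcodes
#' @param counts named integer vector from [count_barcodes()]
#' @return data.table with columns `observed`, `corrected` (NA = rejected) and
#'   `was_corrected`
#' @export
correct_barcode <- function(observed, whitelist, counts) {
  dt <- data.table(observed = observed, corrected = NA_character_,
                   was_corrected = FALSE)
  exact <- dt$observed %in% whitelist
  dt[which(exact), corrected := observed]
  todo <- which(!exact & !grepl("[^ACGT]", dt$observed))
  if (length(todo)) {
    uo <- unique(dt$observed[todo])
    nb <- hamming1_neighbors(uo)
    nb <- nb[neighbor %in% whitelist]
    nb[, count := counts[neighbor]]
    nb <- nb[!is.na(count) & count >= 1L]
    if (nrow(nb)) {
      pick <- nb[, {
        m <- max(count)
        w <- which(count == m)
        .(corrected = if (length(w) == 1L) neighbor[w] else NA_character_)
      }, by = orig]
      corr <- pick$corrected[match(dt$observed[todo], pick$orig)]
      dt[todo, `:=`(corrected = corr, was_corrected = !is.na(corr))]
    }
  }
  dt[]
}

#' Trim 3' poly(A) tails from tag reads
#'
#' Scans the 3' end for the longest A-run, tolerating one non-A base per
#' `polya_mismatch_per` bases of the run, with a minimum run length before any
#' trimming. Reads whose remaining length falls below
#' `ceiling(L * min_fraction_after_polya)` are rejected. Qualities are trimmed
#' in lockstep.
#'
#' @param seq,qual character vectors (phred+33 qualities), equal lengths
#' @param params a [qa_params()] object
#' @return data.table with columns `seq`, `qual`, `trimmed` (bases removed) and
#'   `accepted`
#' @export
trim_polya <- function(seq, qual = NULL, params = qa_params()) {
  n <- length(seq)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  L <- nchar(seq)
  run <- integer(n)
  for (i in seq_len(n)) {
    ch <- rev(strsplit(seq[i], "", fixed = TRUE)[[1]])
    non_a <- cumsum(ch != "A")
    k <- seq_along(ch)
    ok <- which(non_a <= k %/% params$polya_mismatch_per)
    best <- if (length(ok)) max(ok) else 0L
    # the run must end on an A (never trim a trailing non-A)
    while (best > 0L && ch[best] != "A") best <- best - 1L
    run[i] <- if (best >= params$polya_min_run) best else 0L
  }
  keep <- L - run
  min_keep <- ceiling(L * params$min_fraction_after_polya)
  data.table(
    seq = substr(seq, 1L, keep),
    qual = substr(qual, 1L, keep),
    trimmed = run,
    accepted = keep >= min_keep
  )
}

#' DUST low-complexity score
#'
#' Counts overlapping 3-mers: with `c_t` occurrences of each distinct 3-mer
#' among the `k = L - 2` windows, the score is
#' `sum(c_t * (c_t - 1) / 2) / (k - 1)`. Homopolymers score highest; a read
#' with all-distinct 3-mers scores 0. Sequences shorter than 3 bases (or with
#' k = 1) score 0.
#'
#' @param seq character vector of sequences
#' @return numeric vector of scores
#' @export
dust_score <- function(seq) {
  vapply(seq, function(s) {
    L <- nchar(s)
    if (L < 4L) return(0)
    k <- L - 2L
    tri <- substring(s, 1:k, 3:L)
    ct <- table(tri)
    sum(ct * (ct - 1) / 2) / (k - 1)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Apply per-read QA to tagged reads
#'
#' Runs, in order: cell-barcode correction, UMI ambiguity check, poly(A)
#' trimming with the minimum-remaining-length rule, and the optional DUST
#' low-complexity filter. Rejection reasons are one of `bad_barcode`,
#' `ambiguous_umi`, `short_after_polya`, `low_complexity`.
#'
#' @param reads data.table with columns `barcode`, `umi`, `seq`, `qual`
#' @param whitelist character vector of known barcodes
#' @param counts named integer vector from [count_barcodes()]; computed from
#'   `reads$barcode` when missing
#' @param params a [qa_params()] object
#' @return the input with added columns `corrected_barcode`, `was_corrected`,
#'   `seq`/`qual` (trimmed), `accepted`, `reason` (NA when accepted)
#' @export
qa_reads <- function(reads, whitelist, counts = NULL, params = qa_params()) {
  reads <- as.data.table(reads)
  if (is.null(counts)) counts <- count_barcodes(reads$barcode, whitelist)
  out <- copy(reads)
  corr <- correct_barcode(out$barcode, whitelist, counts)
  out[, corrected_barcode := corr$corrected]
  out[, was_corrected := corr$was_corrected]
  out[, reason := NA_character_]
  out[is.na(corrected_barcode), reason := "bad_barcode"]
  out[is.na(reason) & grepl("[^ACGT]", umi), reason := "ambiguous_umi"]

  idx <- which(is.na(out$reason))
  if (length(idx)) {
    tr <- trim_polya(out$seq[idx], out$qual[idx], params)
    out[idx, `:=`(seq = tr$seq, qual = tr$qual)]
    out[idx[!tr$accepted], reason := "short_after_polya"]
  }
  if (!is.null(params$dust_threshold)) {
    idx <- which(is.na(out$reason))
    if (length(idx)) {
      sc <- dust_score(out$seq[idx])
      out[idx[sc > params$dust_threshold], reason := "low_complexity"]
    }
  }
  out[, accepted := is.na(reason)]
  out[]
}

#' Read a 10x-style FASTQ pair into a tagged-read table
#'
#' R1 carries barcode + UMI, R2 the cDNA tag. Requires the `ShortRead` package.
#'
#' @param r1,r2 FASTQ paths (gzip transparent)
#' @param barcode_length,umi_length chemistry lengths (16 + 10 for 10x v2)
#' @return data.table with `read_id`, `barcode`, `umi`, `seq`, `qual`
#' @export
read_tag_fastq <- function(r1, r2, barcode_length = 16L, umi_length = 10L) {
  if (!requireNamespace("ShortRead", quietly = TRUE)) {
    stop("read_tag_fastq requires the ShortRead package")
  }
  f1 <- ShortRead::readFastq(r1)
  f2 <- ShortRead::readFastq(r2)
  if (length(f1) != length(f2)) stop("FASTQ pair lengths differ")
  s1 <- as.character(ShortRead::sread(f1))
  data.table(
    read_id = seq_along(f1),
    barcode = substr(s1, 1L, barcode_length),
    umi = substr(s1, barcode_length + 1L, barcode_length + umi_length),
    seq = as.character(ShortRead::sread(f2)),
    qual = as.character(Biostrings::quality(Biostrings::quality(f2)))
  )
}
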