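# Strand- and barcode-aware pileup over collapsed molecules or raw tag reads,
# SNV filtering, bi-allelic/strand refinement, edit/germline annotation,
# per-cell quantification and per-molecule SNV co-expression.

#' SNV filter parameters
#'
#' @param min_base_quality count a base only when its quality is at least this
#'   (default 20)
#' @param min_barcodes minimum unique cell barcodes covering a site (default 5)
#' @param min_alt_barcodes minimum unique barcodes supporting the alternative
#'   allele (default 2)
#' @param min_maf minimum minor allele fraction: total alternative bases over
#'   total bases summed across cells (default 0.01)
#' @param end_exclusion a call needs at least one supporting mismatch at least
#'   this many bases away from the nearest read end; internal read-ends of
#'   collapsed molecules count as ends (default 5)
#' @param af_cutoff optional stricter allele-fraction cutoff applied by
#'   [apply_af_cutoff()] for germline-focused analyses (default 0.25)
#' @return list of class `snv_filter_params`
#' @export
snv_filter_params <- function(min_base_quality = 20L, min_barcodes = 5L,
                              min_alt_barcodes = 2L, min_maf = 0.01,
                              end_exclusion = 5L, af_cutoff = 0.25) {
  stopifnot(min_alt_barcodes <= min_barcodes, min_maf >= 0, min_maf <= af_cutoff)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_barcodes = as.integer(min_barcodes),
                 min_alt_barcodes = as.integer(min_alt_barcodes),
                 min_maf = min_maf,
                 end_exclusion = as.integer(end_exclusion),
                 af_cutoff = af_cutoff),
            class = "snv_filter_params")
}

# internal: per-record M segments with global offsets into the concatenated
# sequence/quality strings
.pileup_segments <- function(rec) {
  segs <- aln_segments(rec$pos, rec$cigar)
  seq_off <- cumsum(nchar(rec$seq)) - nchar(rec$seq)
  segs[, contig := rec$contig[aln_id]]
  segs[, goff := seq_off[aln_id] + q_start]
  segs
}

#' Barcode- and strand-aware pileup
#'
#' Discovers candidate sites (positions where at least one record mismatches
#' the reference with base quality at or above the threshold) and tallies, for
#' every candidate site, the qualifying bases of all covering records: one
#' count per collapsed molecule (`dialect = "collapsed"`) or per read
#' (`"tags"`, `"external"`). The external dialect additionally requires
#' maximum mapping quality and a unique gene annotation, and keeps
#' duplicate-flagged reads. Every counted base carries its distance to the
#' nearest read end; for collapsed molecules the molecule span boundaries and
#' internal read-end positions all count as ends.
#'
#' @param records data.table of alignment records: `contig`, `pos` (0-based),
#'   `cigar`, `strand`, `seq`, `qual` (reference-oriented), `barcode`; for the
#'   collapsed dialect an `internal_ends` list column; for the external
#'   dialect `mapq` and `gene_id`
#' @param reference a `ref_index` or [Biostrings::DNAStringSet]
#' @param cells optional character vector restricting the pileup to cell
#'   barcodes
#' @param params [snv_filter_params()]
#' @param dialect one of `"collapsed"`, `"tags"`, `"external"`
#' @param extra_sites optional data.table (`contig`, `pos`) of sites to tally
#'   even without a mismatch (used for known-SNV quantification)
#' @param min_base_quality override of the base-quality gate (e.g. 0 for
#'   unfiltered known-site quantification)
#' @return list of class `snv_pileup` with data.tables `sites` (per-site
#'   coverage summary), `alleles` (per site x alternative base), `cell_counts`
#'   (per site x barcode x base) and `base_obs` (per record x site observed
#'   base, feeds co-expression extraction)
#' @export
pileup <- function(records, reference, cells = NULL,
                   params = snv_filter_params(),
                   dialect = c("collapsed", "tags", "external"),
                   extra_sites = NULL,
                   min_base_quality = params$min_base_quality) {
  dialect <- match.arg(dialect)
  genome <- if (inherits(reference, "ref_index")) reference$genome else reference
  rec <- as.data.table(records)
  if (!is.null(cells)) rec <- rec[barcode %in% cells]
  if (dialect == "external") {
    if (!"mapq" %in% names(rec)) stop("external dialect requires a mapq column")
    rec <- rec[mapq == max(mapq) & !is.na(gene_id)]
  }
  if (!nrow(rec)) stop("no records to pile up")
  rec <- copy(rec)
  rec[, rec_id := .I]

  segs <- .pileup_segments(rec)
  all_seq <- charToRaw(paste(rec$seq, collapse = ""))
  all_qual <- as.integer(charToRaw(paste(rec$qual, collapse = ""))) - 33L

  # reference bases for every aligned segment, concatenated in segment order
  ref_str <- ref_chunks(genome, segs$contig, segs$ref_start, segs$ref_end)
  ref_raw <- charToRaw(paste(ref_str, collapse = ""))
  exp_off <- cumsum(segs$width) - segs$width
  read_raw_idx <- rep(segs$goff, segs$width) + sequence(segs$width)
  mm <- which(all_seq[read_raw_idx] != ref_raw)

  sites <- data.table(contig = character(), pos = integer())
  if (length(mm)) {
    seg_i <- findInterval(mm, exp_off + 1L)
    within <- mm - exp_off[seg_i] - 1L
    mq <- all_qual[read_raw_idx[mm]]
    mb <- all_seq[read_raw_idx[mm]]
    ok <- mq >= min_base_quality & mb != charToRaw("N")
    sites <- unique(data.table(contig = segs$contig[seg_i][ok],
                               pos = segs$ref_start[seg_i][ok] + within[ok]))
  }
  if (!is.null(extra_sites)) {
    sites <- unique(rbindlist(list(sites,
                                   as.data.table(extra_sites)[, .(contig, pos)])))
  }
  setorder(sites, contig, pos)
  if (!nrow(sites)) {
    return(structure(list(sites = data.table(), alleles = data.table(),
                          cell_counts = data.table(), base_obs = data.table(),
                          dialect = dialect, params = params),
                     class = "snv_pileup"))
  }

  # all covering (segment, site) pairs
  s2 <- copy(segs)[, `:=`(start = ref_start, end = ref_end, seg_id = .I)]
  setkey(s2, contig, start, end)
  q <- copy(sites)[, `:=`(start = pos, end = pos + 1L)]
  ov <- data.table::foverlaps(q, s2, type = "within", nomatch = NULL)
  if (!nrow(ov)) stop("internal error: sites without covering segments")

  obs <- data.table(
    rec_id = ov$aln_id,
    contig = ov$contig,
    pos = ov$pos,
    qoff = ov$q_start + (ov$pos - ov$ref_start),
    goff = ov$goff + (ov$pos - ov$ref_start)
  )
  obs[, base := rawToChar(all_seq[goff + 1L], multiple = TRUE)]
  obs[, qual := all_qual[goff + 1L]]
  obs[, barcode := rec$barcode[rec_id]]
  obs[, strand := rec$strand[rec_id]]

  # distance to the nearest read end
  if (dialect == "collapsed") {
    rspan <- segs[, .(span_start = min(ref_start), span_end = max(ref_end)),
                  by = aln_id]
    obs[rspan, on = c(rec_id = "aln_id"),
        end_dist := pmin(pos - i.span_start, i.span_end - 1L - pos)]
    if ("internal_ends" %in% names(rec)) {
      has_ie <- which(vapply(rec$internal_ends, length, integer(1)) > 0L)
      if (length(has_ie)) {
        sub <- which(obs$rec_id %in% has_ie)
        if (length(sub)) {
          d <- mapply(function(p, r) min(abs(p - rec$internal_ends[[r]])),
                      obs$pos[sub], obs$rec_id[sub])
          obs[sub, end_dist := pmin(end_dist, as.integer(d))]
        }
      }
    }
  } else {
    L <- nchar(rec$seq)
    obs[, end_dist := pmin(qoff, L[rec_id] - 1L - qoff)]
  }

  obs[, c("qoff", "goff") := NULL]
  obs <- obs[qual >= min_base_quality & base != "N"]

  sites[, ref := ref_chunks(genome, contig, pos, pos + 1L)]
  obs[sites, on = c("contig", "pos"), ref := i.ref]

  site_sum <- obs[, .(
    n_barcodes = data.table::uniqueN(barcode),
    total_bases = .N,
    ref_bases = sum(base == ref),
    plus_mols = sum(strand == "+"),
    minus_mols = sum(strand == "-")
  ), by = .(contig, pos, ref)]

  alleles <- obs[base != ref, .(
    alt_bases = .N,
    n_barcodes_alt = data.table::uniqueN(barcode),
    alt_plus = sum(strand == "+"),
    alt_minus = sum(strand == "-"),
    max_end_dist = max(end_dist)
  ), by = .(contig, pos, ref, alt = base)]

  cell_counts <- obs[, .(count = .N,
                         count_plus = sum(strand == "+"),
                         count_minus = sum(strand == "-")),
                     by = .(contig, pos, ref, barcode, base)]

  structure(list(sites = site_sum[], alleles = alleles[],
                 cell_counts = cell_counts[], base_obs = obs[],
                 dialect = dialect, params = params),
            class = "snv_pileup")
}

#' @export
print.snv_pileup <- function(x, ...) {
  cat("snv_pileup (", x$dialect, "): ", nrow(x$sites), " candidate sites, ",
      nrow(x$alleles), " site/alt pairs\n", sep = "")
  invisible(x)
}

#' Call SNVs from a pileup
#'
#' Emits one call per site/alternative-allele pair passing all filters: at
#' least `min_barcodes` unique cell barcodes covering the site, at least
#' `min_alt_barcodes` unique barcodes with the alternative allele, minor
#' allele fraction at least `min_maf`, and at least one supporting mismatch at
#' least `end_exclusion` bases from the nearest read end.
#'
#' @param pu an `snv_pileup`
#' @param params [snv_filter_params()]
#' @return data.table of calls with counts, `maf` and strand tallies
#' @export
call_snvs <- function(pu, params = pu$params) {
  if (!nrow(pu$alleles)) return(data.table())
  calls <- merge(pu$alleles,
                 pu$sites[, .(contig, pos, n_barcodes, total_bases, ref_bases,
                              plus_mols, minus_mols)],
                 by = c("contig", "pos"))
  calls[, maf := alt_bases / total_bases]
  calls <- calls[n_barcodes >= params$min_barcodes &
                   n_barcodes_alt >= params$min_alt_barcodes &
                   maf >= params$min_maf &
                   max_end_dist >= params$end_exclusion]
  setorder(calls, contig, pos, alt)
  calls[]
}

#' Apply the stricter allele-fraction cutoff
#'
#' Retains calls with `maf` strictly above the cutoff. Intended for
#' germline-focused analyses; A>G edit discovery should skip it, as edits are
#' progressively lost with increasing allele-fraction cutoffs.
#'
#' @param calls from [call_snvs()]
#' @param cutoff allele-fraction cutoff (default 0.25, strict `>`)
#' @return the filtered calls
#' @export
apply_af_cutoff <- function(calls, cutoff = 0.25) {
  as.data.table(calls)[maf > cutoff]
}

#' Bi-allelic refinement flag
#'
#' A call is bi-allelic when reference plus alternative bases make up at least
#' `min_fraction` of all bases observed at the site.
#'
#' @param ref_bases,alt_bases,total_bases per-call base tallies
#' @param min_fraction default 0.95
#' @return logical vector
#' @export
refine_biallelic <- function(ref_bases, alt_bases, total_bases,
                             min_fraction = 0.95) {
  (ref_bases + alt_bases) / total_bases >= min_fraction
}

#' Infer the transcribed strand of a call
#'
#' 10x 3' libraries are strand-specific, so a genuine transcript-derived SNV
#' should be covered almost exclusively from one strand. Returns the strand
#' carrying at least `min_fraction` of the covering molecules, else
#' `"unknown"`.
#'
#' @param plus_mols,minus_mols covering molecule counts by alignment strand
#' @param min_fraction default 0.90
#' @return character vector in `c("+", "-", "unknown")`
#' @export
infer_strand <- function(plus_mols, minus_mols, min_fraction = 0.90) {
  tot <- plus_mols + minus_mols
  out <- rep("unknown", length(tot))
  out[plus_mols >= min_fraction * tot & tot > 0] <- "+"
  out[minus_mols >= min_fraction * tot & tot > 0] <- "-"
  out
}

#' Annotate SNV calls
#'
#' Adds the bi-allelic flag, the inferred strand, and annotation classes:
#' `AG_edit` when the strand-oriented change is A>G (i.e. A>G on `+`, T>C on
#' the reference for `-`) and the site is in the edit catalogue or inside an
#' Alu-like repeat interval; `germline` when matching the matched-DNA call
#' set; `thousand_genomes` when matching a common-SNP record with the same
#' alternative allele. The primary `annotation` column uses the precedence
#' germline > thousand_genomes > AG_edit > unknown.
#'
#' @param calls from [call_snvs()]
#' @param edit_catalogue data.table (`contig`, `pos`) of known RNA-edit sites
#' @param repeats data.table (`contig`, `start`, `end`) of Alu-like repeats,
#'   0-based half-open
#' @param common_snps data.table (`contig`, `pos`, `alt`) of common SNPs
#' @param germline data.table (`contig`, `pos`, `alt`) of matched-DNA calls
#' @param biallelic_min,strand_min refinement thresholds (0.95 and 0.90)
#' @return the calls with added columns `biallelic_ok`, `strand`, `is_AG`,
#'   `in_catalogue`, `in_repeat`, `is_edit`, `is_germline`, `is_1kg`,
#'   `annotation`
#' @export
annotate_calls <- function(calls, edit_catalogue = NULL, repeats = NULL,
                           common_snps = NULL, germline = NULL,
                           biallelic_min = 0.95, strand_min = 0.90) {
  calls <- copy(as.data.table(calls))
  if (!nrow(calls)) return(calls)
  calls[, biallelic_ok := refine_biallelic(ref_bases, alt_bases, total_bases,
                                           biallelic_min)]
  calls[, strand := infer_strand(plus_mols, minus_mols, strand_min)]
  calls[, is_AG := (strand == "+" & ref == "A" & alt == "G") |
          (strand == "-" & ref == "T" & alt == "C")]

  calls[, in_catalogue := FALSE]
  if (!is.null(edit_catalogue) && nrow(edit_catalogue)) {
    ec <- as.data.table(edit_catalogue)
    calls[ec, on = c("contig", "pos"), in_catalogue := TRUE]
  }
  calls[, in_repeat := FALSE]
  if (!is.null(repeats) && nrow(repeats)) {
    rp <- as.data.table(repeats)[, .(contig, start, end)]
    setkey(rp, contig, start, end)
    q <- data.table(contig = calls$contig, start = calls$pos,
                    end = calls$pos + 1L)
    hit <- !is.na(data.table::foverlaps(q, rp, type = "within",
                                        by.x = c("contig", "start", "end"),
                                        which = TRUE, mult = "first"))
    calls[, in_repeat := hit]
  }
  calls[, is_edit := is_AG & (in_catalogue | in_repeat)]

  calls[, is_germline := FALSE]
  if (!is.null(germline) && nrow(germline)) {
    calls[as.data.table(germline), on = c("contig", "pos", "alt"),
          is_germline := TRUE]
  }
  calls[, is_1kg := FALSE]
  if (!is.null(common_snps) && nrow(common_snps)) {
    calls[as.data.table(common_snps), on = c("contig", "pos", "alt"),
          is_1kg := TRUE]
  }
  calls[, annotation := fifelse(is_germline, "germline",
                         fifelse(is_1kg, "thousand_genomes",
                          fifelse(is_edit, "AG_edit", "unknown")))]
  calls[]
}

#' Quantify known SNV sites per cell
#'
#' Unfiltered per-barcode, per-strand reference/alternative counts at a given
#' site list (no coverage, barcode or allele-fraction gates; base quality gate
#' optional and off by default).
#'
#' @param records,reference,cells,dialect as in [pileup()]
#' @param sites data.table (`contig`, `pos`) and optionally `alt`; when `alt`
#'   is present counts are split ref/alt/other against it
#' @param min_base_quality default 0 (count everything)
#' @return list with `cell_counts` (long table) and `matrices`: sparse
#'   site x barcode `ref` and `alt` count matrices (alt only when `sites$alt`
#'   is given)
#' @export
quantify_known <- function(records, reference, sites, cells = NULL,
                           dialect = "collapsed", min_base_quality = 0L) {
  sites <- as.data.table(sites)
  bad <- sites[pos < 0L]
  genome <- if (inherits(reference, "ref_index")) reference$genome else reference
  clen <- setNames(Biostrings::width(genome), names(genome))
  oob <- sites[!contig %in% names(genome) | pos >= clen[contig]]
  if (nrow(oob)) {
    warning(nrow(oob), " known site(s) outside the reference were skipped")
    sites <- sites[!oob, on = c("contig", "pos")]
  }
  pu <- pileup(records, reference, cells = cells,
               params = snv_filter_params(min_base_quality = 0L),
               dialect = dialect, extra_sites = sites[, .(contig, pos)],
               min_base_quality = min_base_quality)
  cc <- pu$cell_counts[sites[, .(contig, pos)], on = c("contig", "pos"),
                       nomatch = NULL]
  barcodes <- if (is.null(cells)) sort(unique(cc$barcode)) else cells
  key <- sites[, paste(contig, pos, sep = ":")]
  mk <- function(sub) {
    Matrix::sparseMatrix(
      i = match(paste(sub$contig, sub$pos, sep = ":"), key),
      j = match(sub$barcode, barcodes),
      x = sub$count, dims = c(length(key), length(barcodes)),
      dimnames = list(key, barcodes))
  }
  mats <- list(ref = mk(cc[base == ref]))
  if ("alt" %in% names(sites)) {
    cc[sites, on = c("contig", "pos"), site_alt := i.alt]
    mats$alt <- mk(cc[base == site_alt])
  }
  list(cell_counts = cc[], matrices = mats)
}

#' Extract per-molecule SNV co-expression sets
#'
#' For every molecule (or read, in tags mode) the set of called SNV
#' alternative alleles it carries is collected; unique sets with at least
#' `min_snvs` SNVs are reported with per-annotation-class counts, the dominant
#' class when one exceeds half of the set, and its purity.
#'
#' @param base_obs the `base_obs` table of an [pileup()] result
#' @param calls annotated calls from [annotate_calls()]
#' @param min_snvs minimum SNVs per set (default 5)
#' @return data.table: one row per unique co-expressed SNV set with `n_snvs`,
#'   class counts, `dominant_type` (NA when none exceeds half), `purity` and
#'   `n_molecules` sharing the set
#' @export
extract_coexpression <- function(base_obs, calls, min_snvs = 5L) {
  calls <- as.data.table(calls)
  if (!nrow(calls) || !nrow(base_obs)) return(data.table())
  hits <- merge(base_obs, calls[, .(contig, pos, alt, annotation)],
                by.x = c("contig", "pos", "base"),
                by.y = c("contig", "pos", "alt"))
  if (!nrow(hits)) return(data.table())
  # collapse germline-like classes for dominance accounting
  hits[, cls := fifelse(annotation %in% c("germline", "thousand_genomes"),
                        "germline", annotation)]
  per_mol <- hits[, .(
    set_key = paste(sort(unique(paste(contig, pos, base, sep = ":"))),
                    collapse = ","),
    n_snvs = data.table::uniqueN(paste(contig, pos, base)),
    n_germline = data.table::uniqueN(paste(contig, pos, base)[cls == "germline"]),
    n_edit = data.table::uniqueN(paste(contig, pos, base)[cls == "AG_edit"]),
    n_unknown = data.table::uniqueN(paste(contig, pos, base)[cls == "unknown"])
  ), by = rec_id]
  per_mol <- per_mol[n_snvs >= min_snvs]
  if (!nrow(per_mol)) return(data.table())
  sets <- per_mol[, .(n_molecules = .N,
                      n_snvs = n_snvs[1L],
                      n_germline = n_germline[1L],
                      n_edit = n_edit[1L],
                      n_unknown = n_unknown[1L]),
                  by = set_key]
  sets[, `:=`(dominant_type = NA_character_, purity = NA_real_)]
  cnts <- as.matrix(sets[, .(germline = n_germline, AG_edit = n_edit,
                             unknown = n_unknown)])
  mx <- apply(cnts, 1L, max)
  wm <- colnames(cnts)[apply(cnts, 1L, which.max)]
  dom <- mx > sets$n_snvs / 2
  sets[dom, `:=`(dominant_type = wm[dom], purity = mx[dom] / n_snvs)]
  setorder(sets, -n_snvs)
  sets[]
}

#' Reference coverage track of alignment records
#'
#' Per-position depth over the aligned (M) segments of the records; positions
#' with zero coverage are omitted. Feeds the eligible-position screen of
#' [simulate_homozygous_snvs()].
#'
#' @param records alignment or molecule table with `contig`, `pos`, `cigar`
#' @return data.table with `contig`, `pos` (0-based) and `cov`
#' @export
coverage_track <- function(records) {
  rec <- as.data.table(records)
  segs <- aln_segments(rec$pos, rec$cigar)
  segs[, contig := rec$contig[aln_id]]
  out <- lapply(unique(segs$contig), function(ct) {
    s <- segs[contig == ct]
    cv <- IRanges::coverage(IRanges::IRanges(s$ref_start + 1L, s$ref_end))
    v <- S4Vectors::runValue(cv)
    l <- S4Vectors::runLength(cv)
    ends <- cumsum(l)
    starts <- ends - l + 1L
    keep <- v > 0L
    data.table(contig = ct,
               pos = unlist(mapply(seq, starts[keep], ends[keep],
                                   SIMPLIFY = FALSE)) - 1L,
               cov = rep(v[keep], l[keep]))
  })
  rbindlist(out)
}
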