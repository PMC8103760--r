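# Deterministic synthetic droplet scRNA-seq generator: toy genome + gene
# models, cell population, tagged molecules with UMI and PCR duplicates,
# 3'-biased fragment positions, planted germline SNVs and clustered A>G
# edits, gold alignments, and exact bookkeeping of the expected pipeline
# output ("truth").

#' Synthetic dataset configuration
#'
#' Defaults describe the validation fixture used throughout the test suite:
#' 200 multi-exon genes, 500 cells at ~200 molecules per cell with a
#' geometric molecular-duplicate distribution, 20% PCR duplication, zero
#' sequencing/UMI/barcode error rates, 50 homozygous and 50 heterozygous
#' (allele fraction 0.5) SNVs, and three 10-edit hyper-edited clusters whose
#' 150 bp span exceeds the 98 bp read length (so no single fragment can see a
#' whole cluster).
#'
#' @param ... named overrides of any default
#' @return list of class `synth_config`
#' @export
synth_config <- function(...) {
  cfg <- list(
    # reference
    n_genes = 200L, genes_per_contig = 50L,
    exons_per_gene = c(2L, 5L), exon_length = c(100L, 400L),
    intron_length = c(200L, 1500L), intergenic_gap = c(500L, 2000L),
    excluded_tx_fraction = 0.05, short_tx_fraction = 0.02,
    antisense_overlap_fraction = 0.02,
    n_repeats = 30L, repeat_length = 300L,
    # library
    n_cells = 500L, ambient_barcodes = 200L, whitelist_extra = 100L,
    molecules_per_cell = 200, ambient_molecules = 5,
    barcode_length = 16L, umi_length = 10L,
    umi_dup_max = 8L, umi_dup_prob = 0.5, umi_dup_fixed = NULL,
    pcr_duplicate_rate = 0.2,
    read_length = 98L, three_prime_scale = 200,
    fraction_intronic = 0.1,
    base_error_rate = 0, umi_error_rate = 0, barcode_error_rate = 0,
    # planted variants
    n_hom = 50L, n_het = 50L, het_af = 0.5,
    n_edit_clusters = 3L, edits_per_cluster = 10L,
    cluster_span = 150L, edited_fraction = 0.3
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown synth_config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "synth_config")
}

.rand_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Generate a toy reference: genome sequences plus gene models
#'
#' Lays out multi-exon genes on both strands across a few contigs, adds a
#' sprinkling of transcripts with excluded biotypes and sub-100 bp
#' transcripts (exercising the index filters), occasional antisense genes
#' inside host introns (overlapping gene pairs), and Alu-like repeat
#' intervals. Deterministic under `seed`.
#'
#' @param config a [synth_config()]
#' @param seed integer seed
#' @return list of class `synth_reference`: `genome` (DNAStringSet), `genes`,
#'   `transcripts`, `exons` (GTF-shaped, 0-based half-open), `chains`
#'   (per-transcript exon chains in transcript orientation with cumulative
#'   offsets), `repeats`, `config`
#' @export
generate_reference <- function(config = synth_config(), seed = 1L) {
  set.seed(derive_seed(seed, 1L))
  cfg <- config
  n_contig <- ceiling(cfg$n_genes / cfg$genes_per_contig)
  genes <- list(); exons <- list(); transcripts <- list()
  gi <- 0L
  contig_len <- integer(n_contig)
  for (ci in seq_len(n_contig)) {
    contig <- sprintf("chr%d", ci)
    cursor <- 1000L
    n_here <- min(cfg$genes_per_contig, cfg$n_genes - (ci - 1L) * cfg$genes_per_contig)
    for (k in seq_len(n_here)) {
      gi <- gi + 1L
      gid <- sprintf("G%04d", gi)
      tid <- sprintf("T%04d", gi)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1L)
      ex_len <- sample(seq(cfg$exon_length[1], cfg$exon_length[2]), n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) {
        sample(seq(cfg$intron_length[1], cfg$intron_length[2]), n_ex - 1L, replace = TRUE)
      } else integer(0)
      starts <- cursor + c(0L, cumsum(ex_len[-n_ex] + in_len))
      ends <- starts + ex_len
      genes[[length(genes) + 1L]] <- data.table(
        gene_id = gid, contig = contig, strand = strand,
        start = starts[1], end = ends[n_ex], biotype = "protein_coding")
      exons[[length(exons) + 1L]] <- data.table(
        gene_id = gid, transcript_id = tid, contig = contig, strand = strand,
        start = starts, end = ends, biotype = "protein_coding")
      transcripts[[length(transcripts) + 1L]] <- data.table(
        transcript_id = tid, gene_id = gid, contig = contig, strand = strand,
        biotype = "protein_coding", main = TRUE)

      if (stats::runif(1) < cfg$excluded_tx_fraction) {
        # retained-intron transcript spanning the whole gene
        tid2 <- paste0(tid, "R")
        exons[[length(exons) + 1L]] <- data.table(
          gene_id = gid, transcript_id = tid2, contig = contig, strand = strand,
          start = starts[1], end = ends[n_ex], biotype = "retained_intron")
        transcripts[[length(transcripts) + 1L]] <- data.table(
          transcript_id = tid2, gene_id = gid, contig = contig, strand = strand,
          biotype = "retained_intron", main = FALSE)
      }
      if (stats::runif(1) < cfg$short_tx_fraction) {
        tid3 <- paste0(tid, "S")
        exons[[length(exons) + 1L]] <- data.table(
          gene_id = gid, transcript_id = tid3, contig = contig, strand = strand,
          start = starts[1], end = starts[1] + 80L, biotype = "protein_coding")
        transcripts[[length(transcripts) + 1L]] <- data.table(
          transcript_id = tid3, gene_id = gid, contig = contig, strand = strand,
          biotype = "protein_coding", main = FALSE)
      }
      if (n_ex > 1L && in_len[1] >= 400L &&
            stats::runif(1) < cfg$antisense_overlap_fraction) {
        # single-exon antisense gene inside the first intron of the host
        gi <- gi + 1L
        gid2 <- sprintf("G%04dA", gi)
        tid4 <- sprintf("T%04dA", gi)
        astrand <- setdiff(c("+", "-"), strand)
        a0 <- ends[1] + 100L
        genes[[length(genes) + 1L]] <- data.table(
          gene_id = gid2, contig = contig, strand = astrand,
          start = a0, end = a0 + 200L, biotype = "protein_coding")
        exons[[length(exons) + 1L]] <- data.table(
          gene_id = gid2, transcript_id = tid4, contig = contig,
          strand = astrand, start = a0, end = a0 + 200L,
          biotype = "protein_coding")
        transcripts[[length(transcripts) + 1L]] <- data.table(
          transcript_id = tid4, gene_id = gid2, contig = contig,
          strand = astrand, biotype = "protein_coding", main = TRUE)
      }
      cursor <- ends[n_ex] +
        sample(seq(cfg$intergenic_gap[1], cfg$intergenic_gap[2]), 1L)
    }
    contig_len[ci] <- cursor + 1000L
  }
  genes <- rbindlist(genes)
  exons <- rbindlist(exons)
  transcripts <- rbindlist(transcripts)

  genome <- Biostrings::DNAStringSet(vapply(contig_len, .rand_dna, character(1)))
  names(genome) <- sprintf("chr%d", seq_len(n_contig))

  # exon chains in transcript orientation with cumulative transcript offsets
  chains <- exons[, {
    o <- if (strand[1] == "+") order(start) else order(-start)
    .(rank = seq_along(o), start = start[o], end = end[o],
      gene_id = gene_id[1], contig = contig[1], strand = strand[1])
  }, by = transcript_id]
  chains[, width := end - start]
  chains[, cum := cumsum(width) - width, by = transcript_id]

  # Alu-like repeats inside random gene spans
  host <- genes[sample(.N, min(cfg$n_repeats, .N))]
  repeats <- host[, .(
    contig,
    start = start + sample(0:200, .N, replace = TRUE),
    name = "AluY")]
  repeats[, end := start + cfg$repeat_length]
  data.table::setcolorder(repeats, c("contig", "start", "end", "name"))

  structure(list(genome = genome, genes = genes, transcripts = transcripts,
                 exons = exons, chains = chains, repeats = repeats,
                 config = cfg), class = "synth_reference")
}

#' @export
print.synth_reference <- function(x, ...) {
  cat("synth_reference:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts on", length(x$genome), "contigs\n")
  invisible(x)
}

# transcript sequences (sense strand) for a synth_reference
.tx_seqs <- function(ref, tx_ids = NULL) {
  ch <- ref$chains
  if (!is.null(tx_ids)) ch <- ch[transcript_id %in% tx_ids]
  segs <- ref_chunks(ref$genome, ch$contig, ch$start, ch$end)
  minus <- ch$strand == "-"
  segs[minus] <- revcomp(segs[minus])
  ch2 <- data.table(transcript_id = ch$transcript_id, rank = ch$rank, seg = segs)
  setorder(ch2, transcript_id, rank)
  out <- ch2[, .(seq = paste(seg, collapse = "")), by = transcript_id]
  setNames(out$seq, out$transcript_id)
}

# Map transcript-space intervals [s, e) on ONE transcript to genomic blocks.
# chain: that transcript's chain rows ordered by rank (with cum/width).
# Vectorised over intervals; returns long data.table (row, gstart, gend)
# with blocks in ascending genomic order within each row.
.tx_to_blocks <- function(chain, s, e) {
  k1 <- findInterval(s, chain$cum)
  k2 <- findInterval(e - 1L, chain$cum)
  plus <- chain$strand[1] == "+"
  nblk <- k2 - k1 + 1L
  out <- vector("list", max(nblk))
  for (j in seq_len(max(nblk))) {
    sel <- which(nblk >= j)
    k <- k1[sel] + j - 1L
    ts <- pmax(s[sel], chain$cum[k])
    te <- pmin(e[sel], chain$cum[k] + chain$width[k])
    if (plus) {
      gs <- chain$start[k] + (ts - chain$cum[k])
      ge <- gs + (te - ts)
    } else {
      ge <- chain$end[k] - (ts - chain$cum[k])
      gs <- ge - (te - ts)
    }
    out[[j]] <- data.table(row = sel, gstart = as.integer(gs), gend = as.integer(ge))
  }
  blk <- rbindlist(out)
  setorder(blk, row, gstart)
  blk
}

#' Plant variants into the synthetic reference
#'
#' Chooses host genes (at most one variant or cluster per gene, never a gene
#' from an antisense-overlap pair), transcript-space positions, and
#' alternative alleles. Homozygous variants go onto every molecule of the
#' gene, heterozygous ones onto each molecule independently with the
#' configured allele fraction, and each edit cluster places
#' `edits_per_cluster` strand-oriented A>G edits inside a
#' `cluster_span`-wide transcript window.
#'
#' @param ref a `synth_reference`
#' @param config its [synth_config()]
#' @param seed integer seed
#' @return data.table of variants: `variant_id`, `type` (hom/het/edit),
#'   `gene_id`, `transcript_id`, `tx_pos`, `contig`, `pos` (genomic, 0-based),
#'   `ref`, `alt` (reference-strand), `af`, `cluster_id`
#' @export
plant_variants <- function(ref, config = ref$config, seed = 1L) {
  set.seed(derive_seed(seed, 2L))
  cfg <- config
  main <- ref$transcripts[main == TRUE]
  anti <- ref$genes[grepl("A$", gene_id)]
  excluded_hosts <- character(0)
  if (nrow(anti)) {
    hosts_of <- ref$genes[!grepl("A$", gene_id)]
    ovl <- hosts_of[anti, on = "contig", allow.cartesian = TRUE][
      start < i.end & end > i.start]
    excluded_hosts <- unique(c(anti$gene_id, ovl$gene_id))
  }
  tx_len <- ref$chains[, .(len = sum(width)), by = transcript_id]
  main <- merge(main, tx_len, by = "transcript_id")
  eligible <- main[!gene_id %in% excluded_hosts &
                     len >= 2L * cfg$read_length + cfg$cluster_span]
  need <- cfg$n_hom + cfg$n_het + cfg$n_edit_clusters
  if (nrow(eligible) < need) stop("not enough eligible genes for planting")
  hosts <- eligible[sample(.N, need)]
  seqs <- .tx_seqs(ref, hosts$transcript_id)

  vlist <- list()
  vid <- 0L
  types <- c(rep("hom", cfg$n_hom), rep("het", cfg$n_het),
             rep("edit", cfg$n_edit_clusters))
  cluster <- 0L
  for (i in seq_len(nrow(hosts))) {
    tid <- hosts$transcript_id[i]
    s <- seqs[[tid]]
    L <- hosts$len[i]
    ch <- ref$chains[transcript_id == tid][order(rank)]
    minus <- ch$strand[1] == "-"
    if (types[i] %in% c("hom", "het")) {
      tp <- sample(seq(10L, L - 10L), 1L)
      rb <- substr(s, tp + 1L, tp + 1L)
      ab <- sample(setdiff(BASES, rb), 1L)
      bl <- .tx_to_blocks(ch, tp, tp + 1L)
      vid <- vid + 1L
      vlist[[length(vlist) + 1L]] <- data.table(
        variant_id = sprintf("V%03d", vid), type = types[i],
        gene_id = hosts$gene_id[i], transcript_id = tid, tx_pos = tp,
        tx_alt = ab,
        contig = ch$contig[1], pos = bl$gstart[1],
        ref = unname(if (minus) COMPLEMENT[rb] else rb),
        alt = unname(if (minus) COMPLEMENT[ab] else ab),
        af = if (types[i] == "hom") 1.0 else cfg$het_af,
        cluster_id = NA_integer_)
    } else {
      cluster <- cluster + 1L
      # require the edits to spread wider than a read so no single fragment
      # can carry the whole cluster
      min_span <- min(cfg$cluster_span - 30L, cfg$read_length + 20L)
      repeat {
        w0 <- sample(seq(5L, L - cfg$cluster_span - 5L), 1L)
        win <- substr(s, w0 + 1L, w0 + cfg$cluster_span)
        a_pos <- w0 + which(strsplit(win, "")[[1]] == "A") - 1L
        if (length(a_pos) >= cfg$edits_per_cluster &&
              max(a_pos) - min(a_pos) >= min_span) break
      }
      k <- cfg$edits_per_cluster
      inner <- setdiff(a_pos, range(a_pos))
      tp <- sort(c(range(a_pos), sample(inner, k - 2L)))
      for (p in tp) {
        bl <- .tx_to_blocks(ch, p, p + 1L)
        vid <- vid + 1L
        vlist[[length(vlist) + 1L]] <- data.table(
          variant_id = sprintf("V%03d", vid), type = "edit",
          gene_id = hosts$gene_id[i], transcript_id = tid, tx_pos = p,
          tx_alt = "G",
          contig = ch$contig[1], pos = bl$gstart[1],
          ref = if (minus) "T" else "A",
          alt = if (minus) "C" else "G",
          af = NA_real_, cluster_id = cluster)
      }
    }
  }
  out <- rbindlist(vlist)
  setorder(out, contig, pos)
  out[]
}

# whitelist with minimum pairwise Hamming distance 3 so planted 1-mismatch
# barcode errors always correct uniquely
.make_whitelist <- function(n, len) {
  for (attempt in 1:20) {
    bc <- unique(vapply(seq_len(n), function(i) .rand_dna(len), character(1)))
    if (length(bc) < n) next
    m <- matrix(unlist(strsplit(bc, "", fixed = TRUE)), ncol = len, byrow = TRUE)
    matches <- Reduce(`+`, lapply(BASES, function(b) tcrossprod((m == b) * 1L)))
    mism <- len - matches
    diag(mism) <- len
    if (min(mism) >= 3L) return(bc)
  }
  stop("could not build a whitelist with pairwise Hamming distance >= 3")
}

# UMIs for one barcode: unique (sampled without replacement from the 4^len
# space), and no Hamming-1 pair within a gene
.assign_umis <- function(genes, len) {
  n <- length(genes)
  space <- 4L^len
  ints <- sample.int(space, n) - 1L
  to_str <- function(v) {
    cols <- lapply(seq_len(len), function(i) BASES[(v %/% 4L^(i - 1L)) %% 4L + 1L])
    do.call(paste0, cols)
  }
  u <- to_str(ints)
  raws <- lapply(u, charToRaw)
  for (g in unique(genes[duplicated(genes)])) {
    idx <- which(genes == g)
    repeat {
      bad <- integer(0)
      for (i in seq_along(idx)[-1]) {
        for (j in seq_len(i - 1L)) {
          if (sum(raws[[idx[i]]] != raws[[idx[j]]]) <= 1L) bad <- c(bad, idx[i])
        }
      }
      if (!length(bad)) break
      repl <- sample.int(space, length(bad))
      while (any(repl %in% (ints + 1L))) repl <- sample.int(space, length(bad))
      ints[bad] <- repl - 1L
      u[bad] <- to_str(ints[bad])
      raws[bad] <- lapply(u[bad], charToRaw)
    }
  }
  u
}

#' Generate the synthetic sequencing library with gold alignments
#'
#' Draws molecules per cell (and per ambient barcode), assigns barcode-unique
#' UMIs with no Hamming-1 pairs within a barcode/gene (so molecule identity
#' is well-defined and directional collapse is exact), gives each molecule a
#' truncated-geometric number of distinct 3'-biased fragment positions
#' (molecular duplicates) plus PCR copies at identical positions, injects
#' sequencing/UMI/barcode errors at the configured rates, and emits gold
#' alignments (true genomic placements, bypassing any external aligner)
#' together with exact truth bookkeeping. Intronic (unspliced) molecules
#' produce fragments wholly inside one intron; hyper-edited molecules get
#' fragments tiling their cluster window.
#'
#' @param ref a `synth_reference`
#' @param variants from [plant_variants()], or NULL for none
#' @param config a [synth_config()]
#' @param seed integer seed
#' @return list of class `synth_library`: `reads` (gold alignment table with
#'   `read_id`, `barcode`, `barcode_obs`, `umi`, `umi_obs`, `gene_id`,
#'   `mol_id`, `contig`, `pos`, `cigar`, `strand`, `seq`, `qual`, `score`,
#'   `source`), `truth` (list: `molecules`, `barcodes`, `counts`,
#'   `variant_molecules`), `whitelist`, `cells`, `variants`, `config`
#' @export
generate_library <- function(ref, variants = NULL, config = ref$config, seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  cfg <- config
  R <- cfg$read_length

  whitelist <- .make_whitelist(
    cfg$n_cells + cfg$ambient_barcodes + cfg$whitelist_extra, cfg$barcode_length)
  cells <- whitelist[seq_len(cfg$n_cells)]
  ambient <- if (cfg$ambient_barcodes > 0L) {
    whitelist[cfg$n_cells + seq_len(cfg$ambient_barcodes)]
  } else character(0)

  main <- ref$transcripts[main == TRUE]
  tx_len <- ref$chains[, .(len = sum(width)), by = transcript_id]
  main <- merge(main, tx_len, by = "transcript_id")
  main <- main[len >= R + 5L]
  gene_w <- stats::rexp(nrow(main)) + 0.1

  n_mol_cell <- stats::rpois(length(cells), cfg$molecules_per_cell)
  n_mol_amb <- if (length(ambient)) stats::rpois(length(ambient), cfg$ambient_molecules) else integer(0)
  mol <- data.table(barcode = c(rep(cells, n_mol_cell), rep(ambient, n_mol_amb)))
  n_mol <- nrow(mol)
  mol[, mol_id := .I]
  gidx <- sample.int(nrow(main), n_mol, replace = TRUE, prob = gene_w)
  mol[, `:=`(gene_id = main$gene_id[gidx],
             transcript_id = main$transcript_id[gidx],
             tx_len = main$len[gidx],
             strand = main$strand[gidx],
             contig = main$contig[gidx])]

  # intronic (unspliced pre-mRNA) molecules: need an intron at least R long
  introns <- ref$chains[, {
    o <- order(start)
    if (.N > 1L) .(istart = end[o][-.N], iend = start[o][-1L])
    else .(istart = integer(), iend = integer())
  }, by = transcript_id]
  introns <- introns[iend - istart >= R + 2L]
  mol[, intronic := stats::runif(.N) < cfg$fraction_intronic &
        transcript_id %in% introns$transcript_id]

  # variant carriage (haplotype) per molecule; variant hosts stay spliced
  mol[, hap := "ref"]
  edited_genes <- character(0)
  if (!is.null(variants) && nrow(variants)) {
    vhom_genes <- unique(variants[type == "hom", gene_id])
    vhet_genes <- unique(variants[type == "het", gene_id])
    edited_genes <- unique(variants[type == "edit", gene_id])
    mol[gene_id %in% c(vhom_genes, vhet_genes, edited_genes), intronic := FALSE]
    mol[gene_id %in% vhom_genes, hap := "alt"]
    mol[gene_id %in% vhet_genes,
        hap := fifelse(stats::runif(.N) < cfg$het_af, "alt", "ref")]
    mol[gene_id %in% edited_genes,
        hap := fifelse(stats::runif(.N) < cfg$edited_fraction, "edit", "ref")]
  }

  mol[, umi := .assign_umis(gene_id, cfg$umi_length), by = barcode]

  # number of distinct fragment positions (molecular duplicates)
  if (!is.null(cfg$umi_dup_fixed)) {
    u <- rep(as.integer(cfg$umi_dup_fixed), n_mol)
  } else {
    p <- cfg$umi_dup_prob
    u <- sample.int(cfg$umi_dup_max, n_mol, replace = TRUE,
                    prob = p * (1 - p)^(0:(cfg$umi_dup_max - 1L)))
  }
  # hyper-edited molecules carry >= 3 fragments tiling the cluster window
  cl_win <- NULL
  if (length(edited_genes)) {
    cl_win <- variants[type == "edit",
                       .(w0 = min(tx_pos) - 2L, w1 = max(tx_pos) + 2L),
                       by = gene_id]
    u[mol$hap == "edit"] <- pmax(u[mol$hap == "edit"], 3L)
  }
  mol[, n_frag := u]

  frag <- .draw_fragments(mol, introns, cl_win, cfg)

  # PCR copies at identical fragment positions
  copies <- 1L + stats::rgeom(nrow(frag), 1 - cfg$pcr_duplicate_rate)
  frag[, n_copies := copies]
  reads <- frag[rep(seq_len(.N), n_copies)]
  reads[, read_id := .I]

  reads <- merge(reads, mol[, .(mol_id, barcode, umi, gene_id, transcript_id,
                                strand, contig, hap, intronic)],
                 by = "mol_id", sort = FALSE)

  aln <- .gold_alignments(reads, ref, variants, cfg)

  # observed barcode / UMI errors
  aln[, barcode_obs := barcode]
  aln[, umi_obs := umi]
  if (cfg$barcode_error_rate > 0) {
    hit <- which(stats::runif(nrow(aln)) < cfg$barcode_error_rate)
    if (length(hit)) aln[hit, barcode_obs := .mutate_one(barcode_obs)]
  }
  if (cfg$umi_error_rate > 0) {
    hit <- which(stats::runif(nrow(aln)) < cfg$umi_error_rate)
    if (length(hit)) aln[hit, umi_obs := .mutate_one(umi_obs)]
  }

  truth <- .make_truth(mol, reads, frag, variants, cfg)
  structure(list(reads = aln[], truth = truth, whitelist = whitelist,
                 cells = cells, variants = variants, config = cfg),
            class = "synth_library")
}

#' @export
print.synth_library <- function(x, ...) {
  cat("synth_library:", nrow(x$truth$molecules), "molecules,",
      nrow(x$reads), "reads,", length(x$cells), "cells\n")
  invisible(x)
}

# distinct fragment start positions per molecule (transcript coords for
# spliced molecules, genomic coords for intronic ones)
.draw_fragments <- function(mol, introns, cl_win, cfg) {
  R <- cfg$read_length
  idx <- rep(mol$mol_id, mol$n_frag)
  L <- rep(mol$tx_len, mol$n_frag)
  n <- length(idx)
  # 3' bias: distance of the fragment 3' end from the transcript 3' end
  d <- floor(stats::rexp(n, 1 / cfg$three_prime_scale))
  s <- as.integer(pmax(0, L - R - d))
  # valid start range per fragment (transcript coords for spliced molecules)
  fr <- data.table(mol_id = idx, start = s, lo = 0L, hi = as.integer(L - R))

  # intronic molecules: uniform start inside a random long-enough intron
  intr_mol <- mol[intronic == TRUE]
  if (nrow(intr_mol)) {
    im <- merge(fr[mol_id %in% intr_mol$mol_id, .(mol_id)],
                intr_mol[, .(mol_id, transcript_id)], by = "mol_id")[
                  , .SD[1L], by = mol_id]
    pick <- introns[im, on = "transcript_id", allow.cartesian = TRUE]
    pick <- pick[, .SD[sample.int(.N, 1L)], by = mol_id]
    pick[, `:=`(lo = istart + 1L, hi = iend - R - 1L)]
    fr[pick, on = "mol_id", `:=`(lo = i.lo, hi = i.hi)]
    fr[pick, on = "mol_id",
       start := as.integer(lo + floor(stats::runif(.N) * (hi - lo + 1L)))]
  }

  # hyper-edited molecules: first three fragments tile the cluster window,
  # with per-molecule jitter so fragmentation positions (and hence internal
  # read ends) differ between molecules as they would in a real library
  if (!is.null(cl_win)) {
    em <- mol[hap == "edit", .(mol_id, gene_id, tx_len)]
    if (nrow(em)) {
      em <- merge(em, cl_win, by = "gene_id")
      em[, t1 := pmax(0L, w0 - 5L - as.integer(floor(stats::runif(.N) * 15)))]
      em[, t3 := pmin(tx_len - R,
                      pmax(0L, w1 + 6L - R +
                             as.integer(floor(stats::runif(.N) * 15))))]
      em[, t2 := as.integer((t1 + t3) %/% 2L +
                              floor(stats::runif(.N) * 21) - 10L)]
      em[, t2 := pmax(pmax(0L, t3 - R + 1L), pmin(t2, t1 + R - 1L))]
      fr[, frag_i := seq_len(.N), by = mol_id]
      fr[em, on = "mol_id", tile := fifelse(frag_i == 1L, i.t1,
                                     fifelse(frag_i == 2L, i.t2,
                                      fifelse(frag_i == 3L, i.t3, NA_integer_)))]
      fr[!is.na(tile), start := as.integer(tile)]
      fr[, c("frag_i", "tile") := NULL]
    }
  }

  # enforce distinct positions within each molecule (redraw duplicates
  # uniformly inside each fragment's valid range)
  for (iter in 1:100) {
    fr[, dup := duplicated(start), by = mol_id]
    if (!any(fr$dup)) break
    fr[dup == TRUE,
       start := as.integer(lo + floor(stats::runif(.N) * (hi - lo + 1L)))]
  }
  if (anyDuplicated(fr[, .(mol_id, start)])) {
    stop("could not draw distinct fragment positions")
  }
  fr[, c("dup", "lo", "hi") := NULL]
  fr[]
}

.mutate_one <- function(x) {
  L <- nchar(x[1])
  pos <- sample.int(L, length(x), replace = TRUE)
  cur <- substr(x, pos, pos)
  new <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L), character(1))
  paste0(substr(x, 1, pos - 1L), new, substr(x, pos + 1L, L))
}

# build gold alignment records (reference-oriented seq/qual, cigar with N
# skips for spliced reads) for every read copy
.gold_alignments <- function(reads, ref, variants, cfg) {
  R <- cfg$read_length

  # haplotype transcript sequences
  tx_ids <- unique(reads$transcript_id)
  base_seqs <- .tx_seqs(ref, tx_ids)
  hap_tab <- unique(reads[, .(transcript_id, hap)])
  hap_tab[, hap_key := paste(transcript_id, hap, sep = "|")]
  hap_seqs <- setNames(base_seqs[hap_tab$transcript_id], hap_tab$hap_key)
  if (!is.null(variants) && nrow(variants)) {
    for (i in which(hap_tab$hap != "ref")) {
      tid <- hap_tab$transcript_id[i]
      want_type <- if (hap_tab$hap[i] == "alt") c("hom", "het") else "edit"
      vv <- variants[transcript_id == tid & type %in% want_type]
      s <- hap_seqs[[hap_tab$hap_key[i]]]
      for (j in seq_len(nrow(vv))) {
        substr(s, vv$tx_pos[j] + 1L, vv$tx_pos[j] + 1L) <- vv$tx_alt[j]
      }
      hap_seqs[[hap_tab$hap_key[i]]] <- s
    }
  }

  out <- copy(reads)
  out[, hap_key := paste(transcript_id, hap, sep = "|")]

  # spliced reads: sequence from the haplotype transcript, blocks via chain
  spl <- out[intronic == FALSE]
  spl[, seq_sense := substring(hap_seqs[hap_key], start + 1L, start + R)]
  blk_list <- vector("list", length(tx_ids)); names(blk_list) <- tx_ids
  spl[, spl_row := .I]
  for (tid in unique(spl$transcript_id)) {
    ch <- ref$chains[transcript_id == tid][order(rank)]
    sub <- spl[transcript_id == tid]
    bl <- .tx_to_blocks(ch, sub$start, sub$start + R)
    bl[, spl_row := sub$spl_row[row]]
    blk_list[[tid]] <- bl
  }
  blocks <- rbindlist(blk_list)
  setorder(blocks, spl_row, gstart)
  # cigar: widths and N gaps per read
  cig <- blocks[, .(
    pos = gstart[1L],
    cigar = {
      w <- gend - gstart
      if (.N == 1L) paste0(w, "M")
      else {
        gaps <- gstart[-1L] - gend[-.N]
        paste0(paste0(w[-.N], "M", gaps, "N", collapse = ""), w[.N], "M")
      }
    }), by = spl_row]
  spl[cig, on = "spl_row", `:=`(pos = i.pos, cigar = i.cigar)]
  spl[, seq_sam := seq_sense]
  minus <- which(spl$strand == "-")
  if (length(minus)) spl[minus, seq_sam := revcomp(seq_sam)]

  # intronic reads: contiguous genomic fragment, reference sequence
  intr <- out[intronic == TRUE]
  if (nrow(intr)) {
    intr[, pos := start]
    intr[, cigar := paste0(R, "M")]
    intr[, seq_sam := ref_chunks(ref$genome, contig, pos, pos + R)]
  }

  keep <- c("read_id", "mol_id", "barcode", "umi", "gene_id", "contig",
            "pos", "cigar", "strand", "seq_sam")
  aln <- rbindlist(list(spl[, ..keep], if (nrow(intr)) intr[, ..keep]))
  setnames(aln, "seq_sam", "seq")

  # sequencing errors, uniform per base
  if (cfg$base_error_rate > 0) {
    big <- paste(aln$seq, collapse = "")
    raw <- charToRaw(big)
    hit <- which(stats::runif(length(raw)) < cfg$base_error_rate)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      codes <- charToRaw(paste(BASES, collapse = ""))
      cur <- match(raw[hit], codes)
      raw[hit] <- codes[((cur - 1L + shift) %% 4L) + 1L]
      big <- rawToChar(raw)
      off <- cumsum(nchar(aln$seq)) - nchar(aln$seq)
      aln[, seq := substring(big, off + 1L, off + nchar(seq))]
    }
  }

  qv <- sample(30:40, nrow(aln), replace = TRUE)
  aln[, qual := strrep(strsplit(rawToChar(as.raw(qv + 33L)), "")[[1]], nchar(seq))]
  aln[, `:=`(score = nchar(seq), source = "genome")]
  setorder(aln, read_id)
  aln[]
}

# exact bookkeeping of what the pipeline should recover
.make_truth <- function(mol, reads, frag, variants, cfg) {
  R <- cfg$read_length
  per_mol_reads <- reads[, .(n_reads = .N), by = mol_id]
  molecules <- merge(mol[, .(mol_id, barcode, gene_id, transcript_id, umi,
                             n_frag, intronic, hap)],
                     per_mol_reads, by = "mol_id")
  molecules[, n_pcr := n_reads - n_frag]
  molecules[, splice := fifelse(intronic, "unspliced", "spliced")]

  barcodes <- molecules[, .(
    molecules = .N,
    spliced_molecules = sum(splice == "spliced"),
    unspliced_molecules = sum(splice == "unspliced"),
    countable_reads = sum(n_reads),
    pcr_dups = sum(n_pcr)
  ), by = barcode]
  barcodes[, saturation := (countable_reads - molecules) / countable_reads]
  barcodes[, pcr_duplicate_rate := pcr_dups / countable_reads]

  counts <- molecules[, .N, by = .(barcode, gene_id, splice)]

  variant_molecules <- data.table()
  if (!is.null(variants) && nrow(variants)) {
    vm <- merge(molecules[splice == "spliced"],
                variants[, .(variant_id, gene_id, type, tx_pos)],
                by = "gene_id", allow.cartesian = TRUE)
    cov <- merge(frag, vm[, .(mol_id, variant_id, tx_pos)],
                 by = "mol_id", allow.cartesian = TRUE)
    cov <- cov[start <= tx_pos & tx_pos < start + R,
               .(covered = TRUE), by = .(mol_id, variant_id)]
    vm <- merge(vm, cov, by = c("mol_id", "variant_id"), all.x = TRUE)
    vm[is.na(covered), covered := FALSE]
    vm[, carries := covered & ((type %in% c("hom", "het") & hap == "alt") |
                                 (type == "edit" & hap == "edit"))]
    variant_molecules <- vm[, .(variant_id, mol_id, barcode, type, covered,
                                carries)]
  }

  list(molecules = molecules[], barcodes = barcodes[], counts = counts[],
       variant_molecules = variant_molecules)
}
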