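# File-format interop: GTF/FASTA writers for the synthetic reference, FASTQ
# and SAM emission, whitelist/BED/TSV/VCF readers, sparse-matrix and HDF5
# export of pipeline results.

#' Write a synthetic reference to disk
#'
#' Emits the genome FASTA, an Ensembl-dialect GTF (gene/transcript/exon rows
#' with `gene_id`, `transcript_id`, `gene_biotype`, `transcript_biotype`
#' attributes), and a BED file of the Alu-like repeat intervals.
#'
#' @param ref a `synth_reference`
#' @param dir output directory (created if needed)
#' @return named list of written paths
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(ref$genome, fa)

  gtf <- file.path(dir, "genes.gtf")
  rows <- character(0)
  fmt <- function(contig, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            contig, src, type, start + 1L, end, strand, attrs)
  }
  g <- ref$genes
  rows <- c(rows, fmt(g$contig, "synth", "gene", g$start, g$end, g$strand,
                      sprintf('gene_id "%s"; gene_biotype "%s";',
                              g$gene_id, g$biotype)))
  tx_span <- ref$exons[, .(start = min(start), end = max(end),
                           contig = contig[1], strand = strand[1],
                           gene_id = gene_id[1], biotype = biotype[1]),
                       by = transcript_id]
  rows <- c(rows, fmt(tx_span$contig, "synth", "transcript", tx_span$start,
                      tx_span$end, tx_span$strand,
                      sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "protein_coding"; transcript_biotype "%s";',
                              tx_span$gene_id, tx_span$transcript_id,
                              tx_span$biotype)))
  e <- ref$exons
  rows <- c(rows, fmt(e$contig, "synth", "exon", e$start, e$end, e$strand,
                      sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "protein_coding"; transcript_biotype "%s";',
                              e$gene_id, e$transcript_id, e$biotype)))
  writeLines(rows, gtf)

  bed <- file.path(dir, "repeats.bed")
  data.table::fwrite(ref$repeats[, .(contig, start, end, name)], bed,
                     sep = "\t", col.names = FALSE)
  list(fasta = fa, gtf = gtf, repeats = bed)
}

#' Write the planted-edit catalogue as a positional TSV
#'
#' @param variants the variant table of a `synth_library`
#' @param path output TSV (`contig`, `pos` 0-based, `strand`)
#' @export
write_edit_catalogue <- function(variants, path) {
  ed <- as.data.table(variants)[type == "edit", .(contig, pos)]
  ed[, strand := "+"]
  data.table::fwrite(ed, path, sep = "\t")
  invisible(path)
}

#' Read an edit catalogue TSV
#' @param path TSV with columns `contig`, `pos` (0-based), optional `strand`
#' @return data.table
#' @export
read_edit_catalogue <- function(path) {
  data.table::fread(path)
}

#' Read a barcode whitelist (one barcode per line)
#' @param path text file
#' @return character vector
#' @export
read_whitelist <- function(path) {
  readLines(path)
}

#' Read a BED file of intervals
#' @param path BED path (0-based half-open)
#' @return data.table with `contig`, `start`, `end` (plus `name` if present)
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  setnames(dt, seq_len(min(4L, ncol(dt))),
           c("contig", "start", "end", "name")[seq_len(min(4L, ncol(dt)))])
  dt
}

#' Read SNV sites from a VCF
#'
#' Uses `vcfR` when available. Positions are converted to the package's
#' 0-based convention.
#'
#' @param path VCF path
#' @return data.table with `contig`, `pos` (0-based), `ref`, `alt`
#' @export
read_vcf_sites <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_sites requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  data.table(contig = vcfR::getCHROM(v),
             pos = as.integer(vcfR::getPOS(v)) - 1L,
             ref = vcfR::getREF(v),
             alt = vcfR::getALT(v))
}

#' Write SNV sites as a minimal VCF (1-based positions)
#'
#' @param sites data.table with `contig`, `pos` (0-based), `ref`, `alt`
#' @param path output path
#' @param genome optional DNAStringSet for contig headers
#' @export
write_vcf <- function(sites, path, genome = NULL) {
  sites <- as.data.table(sites)
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(genome)) {
             sprintf("##contig=<ID=%s,length=%d>", names(genome),
                     Biostrings::width(genome))
           },
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  sites$contig, sites$pos + 1L, sites$ref, sites$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the library as a 10x-style FASTQ pair
#'
#' R1 carries the (observed) barcode + UMI, R2 the tag read in its original
#' sequencing orientation (reverse-complemented relative to the reference for
#' minus-strand alignments). Requires `ShortRead`.
#'
#' @param lib a `synth_library`
#' @param dir output directory
#' @return list of paths `r1`, `r2`
#' @export
write_library_fastq <- function(lib, dir) {
  if (!requireNamespace("ShortRead", quietly = TRUE)) {
    stop("write_library_fastq requires the ShortRead package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- lib$reads
  ids <- sprintf("read%07d", rd$read_id)
  r1_seq <- paste0(rd$barcode_obs, rd$umi_obs)
  r1 <- file.path(dir, "R1.fastq")
  r2 <- file.path(dir, "R2.fastq")
  sense <- rd$seq
  minus <- which(rd$strand == "-")
  if (length(minus)) sense[minus] <- revcomp(sense[minus])
  q2 <- rd$qual
  q1 <- strrep("I", nchar(r1_seq))
  ShortRead::writeFastq(
    ShortRead::ShortReadQ(sread = Biostrings::DNAStringSet(r1_seq),
                          quality = Biostrings::BStringSet(q1),
                          id = Biostrings::BStringSet(ids)),
    r1, compress = FALSE, mode = "w")
  ShortRead::writeFastq(
    ShortRead::ShortReadQ(sread = Biostrings::DNAStringSet(sense),
                          quality = Biostrings::BStringSet(q2),
                          id = Biostrings::BStringSet(ids)),
    r2, compress = FALSE, mode = "w")
  list(r1 = r1, r2 = r2)
}

#' Write alignment records as SAM (optionally BAM)
#'
#' Emits coordinate-sorted records with the barcode/UMI/gene tags used by the
#' pipeline: `CB` (corrected barcode), `CR` (raw barcode), `UB` (UMI), `GX`
#' (gene), `XA` (read annotation or molecule flag), and for collapsed
#' molecules `NR` (source reads), `NP` (PCR duplicates) and `IE`
#' (comma-separated internal read-end positions).
#'
#' @param rec alignment or molecule table with `contig`, `pos`, `cigar`,
#'   `strand`, `seq`, `qual` and optional tag columns
#' @param genome DNAStringSet for the header
#' @param path output `.sam` path
#' @param bam also convert to BAM via Rsamtools (default FALSE)
#' @return the path written (BAM path when `bam = TRUE`)
#' @export
write_sam <- function(rec, genome, path, bam = FALSE) {
  rec <- as.data.table(rec)
  setorder(rec, contig, pos)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)))
  qname <- if ("read_id" %in% names(rec)) sprintf("r%07d", rec$read_id)
           else sprintf("m%07d", rec$mol_id)
  flag <- ifelse(rec$strand == "-", 16L, 0L)
  tags <- character(nrow(rec))
  add_tag <- function(tags, col, tag, fmt = "Z") {
    if (col %in% names(rec)) {
      paste0(tags, sprintf("\t%s:%s:%s", tag, fmt, as.character(rec[[col]])))
    } else tags
  }
  tags <- add_tag(tags, "barcode", "CB")
  tags <- add_tag(tags, "barcode_obs", "CR")
  tags <- add_tag(tags, "umi", "UB")
  tags <- add_tag(tags, "gene_id", "GX")
  tags <- add_tag(tags, "annotation", "XA")
  tags <- add_tag(tags, "n_reads", "NR", "i")
  tags <- add_tag(tags, "n_pcr_duplicates", "NP", "i")
  if ("internal_ends" %in% names(rec)) {
    ie <- vapply(rec$internal_ends, function(v) paste(v, collapse = ","),
                 character(1))
    has <- nzchar(ie)
    tags[has] <- paste0(tags[has], "\tIE:Z:", ie[has])
  }
  if ("collapsed" %in% names(rec)) {
    tags <- paste0(tags, "\tXC:i:", as.integer(rec$collapsed))
  }
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                   qname, flag, rec$contig, rec$pos + 1L, 60L, rec$cigar,
                   rec$seq, rec$qual, tags)
  writeLines(c(hdr, lines), path)
  if (bam) {
    return(Rsamtools::asBam(path, sub("\\.sam$", "", path),
                            overwrite = TRUE, indexDestination = TRUE))
  }
  invisible(path)
}

#' Read alignment records from SAM/BAM into the pipeline's table form
#'
#' @param path SAM or BAM path
#' @param tags character vector of tags to pull (default the ones written by
#'   [write_sam()])
#' @return data.table with `read_id`, `contig`, `pos` (0-based), `cigar`,
#'   `strand`, `seq`, `qual`, `mapq` plus requested tag columns
#' @export
read_alignments <- function(path, tags = c("CB", "CR", "UB", "GX", "XA")) {
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "strand", "seq", "qual", "mapq"),
    tag = tags)
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  dt <- data.table(
    read_id = seq_along(x$qname),
    qname = x$qname,
    contig = as.character(x$rname),
    pos = x$pos - 1L,
    cigar = x$cigar,
    strand = as.character(x$strand),
    seq = as.character(x$seq),
    qual = as.character(x$qual),
    mapq = x$mapq
  )
  for (tg in tags) {
    v <- x$tag[[tg]]
    if (!is.null(v)) {
      col <- switch(tg, CB = "barcode", CR = "barcode_obs", UB = "umi",
                    GX = "gene_id", XA = "annotation", tg)
      dt[, (col) := v]
    }
  }
  dt
}

#' Export sparse count matrices in MatrixMarket form
#'
#' Writes `spliced.mtx` / `unspliced.mtx` plus `barcodes.tsv` and
#' `genes.tsv`.
#'
#' @param mats list from [count_matrix()]
#' @param dir output directory
#' @export
write_mtx <- function(mats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mats$spliced, file.path(dir, "spliced.mtx"))
  Matrix::writeMM(mats$unspliced, file.path(dir, "unspliced.mtx"))
  writeLines(colnames(mats$spliced), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(mats$spliced), file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Export pipeline metrics and matrices to one HDF5 container
#'
#' Requires the `rhdf5` package; per-barcode metrics go under `/barcodes`,
#' count matrices as CSR-style triplets under `/counts`.
#'
#' @param metrics per-barcode metrics table
#' @param mats list from [count_matrix()]
#' @param path output `.h5` path
#' @export
write_metrics_h5 <- function(metrics, mats, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("write_metrics_h5 requires the rhdf5 package")
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "barcodes")
  metrics <- as.data.table(metrics)
  for (col in names(metrics)) {
    rhdf5::h5write(metrics[[col]], path, paste0("barcodes/", col))
  }
  rhdf5::h5createGroup(path, "counts")
  rhdf5::h5write(rownames(mats$spliced), path, "counts/genes")
  rhdf5::h5write(colnames(mats$spliced), path, "counts/barcodes")
  for (nm in c("spliced", "unspliced")) {
    m <- methods::as(mats[[nm]], "TsparseMatrix")
    rhdf5::h5createGroup(path, paste0("counts/", nm))
    rhdf5::h5write(m@i, path, paste0("counts/", nm, "/i"))
    rhdf5::h5write(m@j, path, paste0("counts/", nm, "/j"))
    rhdf5::h5write(m@x, path, paste0("counts/", nm, "/x"))
    rhdf5::h5write(dim(m), path, paste0("counts/", nm, "/dims"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}
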