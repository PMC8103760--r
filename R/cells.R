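# Cell calling: elbow estimate on spliced molecule counts, then MAD outlier
# filters on per-barcode quality metrics.

#' Elbow candidate estimate from spliced molecule counts
#'
#' The classic knee rule: take the 99th percentile of the spliced molecule
#' counts among the top `expected_cells` barcodes and divide it by 10; every
#' barcode at or above that threshold (and with at least one spliced molecule)
#' is a cell candidate.
#'
#' @param counts named numeric vector: barcode -> spliced molecule count
#' @param expected_cells rough expected number of cells (default 3000); when
#'   larger than the number of barcodes, all barcodes are used
#' @return list with `candidates` (barcodes) and `threshold`
#' @export
elbow_estimate <- function(counts, expected_cells = 3000L) {
  counts <- counts[counts >= 1]
  if (!length(counts)) stop("no barcode with at least one spliced molecule")
  top <- sort(counts, decreasing = TRUE)[seq_len(min(expected_cells, length(counts)))]
  thr <- unname(stats::quantile(top, 0.99, type = 7)) / 10
  list(candidates = names(counts)[counts >= thr], threshold = thr)
}

#' MAD-based metric cutoffs for outlier barcodes
#'
#' All metrics are on the percent scale (0-100) and the MAD is unscaled (no
#' 1.4826 consistency factor). The cutoffs are:
#' * `mt` (mitochondrial percent): maximum `median + min(5 * MAD, 20)`
#' * `saturation`, `pcr` (percent): minimum `median - min(3 * MAD, 10)`
#' * `corrected` (percent of corrected reads): maximum
#'   `median + max(10 * MAD, 1.5)`
#'
#' @param values numeric metric values in percent
#' @param kind one of `"mt"`, `"saturation"`, `"pcr"`, `"corrected"`
#' @return list with `cutoff` and `side` (`"max"` or `"min"`)
#' @export
mad_cutoffs <- function(values, kind = c("mt", "saturation", "pcr", "corrected")) {
  kind <- match.arg(kind)
  values <- values[is.finite(values)]
  med <- stats::median(values)
  mad <- stats::median(abs(values - med))
  switch(kind,
    mt = list(cutoff = med + min(5 * mad, 20), side = "max"),
    saturation = list(cutoff = med - min(3 * mad, 10), side = "min"),
    pcr = list(cutoff = med - min(3 * mad, 10), side = "min"),
    corrected = list(cutoff = med + max(10 * mad, 1.5), side = "max")
  )
}

#' Call cell-containing barcodes
#'
#' Elbow candidates (barcodes with at least one spliced molecule whose count
#' clears the knee threshold) are filtered conjunctively by the four MAD
#' cutoffs, computed over the candidates only: high mitochondrial percent, low
#' saturation, low PCR duplicate rate, and high barcode-corrected read
#' percent. Individual filters can be disabled.
#'
#' @param metrics per-barcode table from [compute_barcode_metrics()]; rate
#'   columns are fractions and are converted to percent internally. The
#'   mitochondrial percent column is `mt_pct` when a gene list named `mt` was
#'   supplied (all zeros otherwise).
#' @param expected_cells see [elbow_estimate()]
#' @param filters character vector naming the MAD filters to apply
#' @return list with `cells` (passing barcodes), `candidates`, `threshold`,
#'   `cutoffs` and a per-candidate data.table `table` with pass/fail reasons
#' @export
call_cells <- function(metrics,
                       expected_cells = 3000L,
                       filters = c("mt", "saturation", "pcr", "corrected")) {
  metrics <- as.data.table(metrics)
  counts <- setNames(as.numeric(metrics$spliced_molecules), metrics$barcode)
  elbow <- elbow_estimate(counts, expected_cells)
  cand <- metrics[barcode %in% elbow$candidates & countable_reads > 0]

  vals <- list(
    mt = if ("mt_pct" %in% names(cand)) cand$mt_pct else rep(0, nrow(cand)),
    saturation = 100 * cand$saturation,
    pcr = 100 * cand$pcr_duplicate_rate,
    corrected = 100 * cand$corrected_read_fraction
  )
  cutoffs <- lapply(names(vals), function(k) mad_cutoffs(vals[[k]], k))
  names(cutoffs) <- names(vals)

  tab <- data.table(barcode = cand$barcode)
  tab[, reasons := ""]
  for (k in filters) {
    co <- cutoffs[[k]]
    fail <- if (co$side == "max") vals[[k]] > co$cutoff else vals[[k]] < co$cutoff
    tab[fail, reasons := paste0(reasons, k, ";")]
  }
  tab[, pass := reasons == ""]
  list(cells = tab[pass == TRUE, barcode],
       candidates = cand$barcode,
       threshold = elbow$threshold,
       cutoffs = cutoffs,
       table = tab[])
}
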