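# Spike-in calibrated absolute abundance: read ratios to 16S rRNA copy
# numbers, per-sample totals, and thresholded richness.

#' Convert ZOTU reads to 16S rRNA copy numbers
#'
#' copies = (zotu_reads / spike_reads) * C * f, where C is the number of
#' extraction spike-in copies added (10,000 or 20,000 depending on batch)
#' and f the inverse proportion of homogenate used in the extraction
#' (5: a 40 ul aliquot of ~200 ul).
#'
#' @param zotu_reads ZOTU read count(s).
#' @param spike_reads Spike-in read count (> 0).
#' @param C Spike-in input copies.
#' @param f Homogenate inverse-proportion factor.
#' @return Estimated copy number(s), real-valued.
#' @export
zotu_copies <- function(zotu_reads, spike_reads, C, f = 5) {
  if (any(spike_reads <= 0)) {
    stop("spike_reads must be positive; samples without spike-in reads are discarded")
  }
  (zotu_reads / spike_reads) * C * f
}

#' Build an absolute abundance table
#'
#' Applies [zotu_copies()] column-wise. Samples with zero spike-in reads
#' are dropped (and listed in `discarded`).
#'
#' @param counts Decontaminated ZOTU x sample read matrix (spike-ins
#'   removed).
#' @param spike_reads Named numeric: spike-in reads per sample.
#' @param spike_copies Named numeric: spike-in input copies per sample.
#' @param f Homogenate factor (scalar or named per sample).
#' @return list: `copies` (ZOTU x sample real matrix), `total` (per-sample
#'   summed copies), `ratio` (symbiont/spike read ratio per sample),
#'   `discarded` (sample ids without spike-in reads).
#' @export
abundance_table <- function(counts, spike_reads, spike_copies, f = 5) {
  samples <- colnames(counts)
  spike_reads <- spike_reads[samples]
  spike_copies <- spike_copies[samples]
  fv <- if (length(f) == 1) rep(f, length(samples)) else f[samples]
  ok <- !is.na(spike_reads) & spike_reads > 0
  discarded <- samples[!ok]
  counts <- counts[, ok, drop = FALSE]
  scale <- (spike_copies[ok] / spike_reads[ok]) * fv[ok]
  copies <- sweep(counts, 2, scale, "*")
  list(copies = copies, total = colSums(copies),
       ratio = colSums(counts) / spike_reads[ok], discarded = discarded)
}

#' Aggregate ZOTU copy numbers to OTUs
#'
#' @param copies ZOTU x sample matrix.
#' @param otu Integer OTU index per ZOTU row.
#' @return OTU x sample matrix (rows `OTU1..` by index).
#' @export
otu_copies <- function(copies, otu) {
  agg <- rowsum(copies, group = otu)
  rownames(agg) <- paste0("OTU", rownames(agg))
  agg
}

#' Per-sample richness above a copy-number threshold
#'
#' Counts taxa with at least `min_copies` estimated copies (inclusive).
#'
#' @param copies Taxa x sample copy matrix (ZOTU- or OTU-level).
#' @param min_copies Threshold in 16S rRNA copies.
#' @return Named integer vector per sample.
#' @export
richness_at_threshold <- function(copies, min_copies = 100) {
  colSums(copies >= min_copies)
}
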