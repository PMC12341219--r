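# Contamination filtering against blank libraries (ratio rule), non-target
# taxon removal, and spike-in read separation.

#' Per-sample relative abundances
#'
#' Converts a ZOTU read-count matrix (rows ZOTUs, columns samples) into
#' percentages: each retained column sums to 100. Empty columns are dropped
#' with a warning.
#'
#' @param counts ZOTU x sample numeric matrix.
#' @return Percentage matrix over the retained samples.
#' @export
to_percentages <- function(counts) {
  cs <- colSums(counts)
  if (any(cs == 0)) {
    warning("dropping empty sample column(s): ",
            paste(colnames(counts)[cs == 0], collapse = ", "))
    counts <- counts[, cs > 0, drop = FALSE]
    cs <- cs[cs > 0]
  }
  sweep(counts, 2, cs, "/") * 100
}

#' Blank-ratio contamination rule
#'
#' A ZOTU is kept only if its percentage in at least one experimental
#' sample is at least `factor` times the maximum percentage it reaches in
#' any blank. ZOTUs absent from all blanks are kept whenever present in an
#' experimental sample. With no blanks supplied, everything is kept with a
#' loud warning.
#'
#' @param pct Percentage matrix from [to_percentages()].
#' @param experimental_ids,blank_ids Column names of experimental and blank
#'   samples (must be disjoint).
#' @param factor Required experimental/blank percentage ratio.
#' @return data.frame: `zotu_id`, `max_sample_pct`, `max_blank_pct`,
#'   `keep`, `reason` (`"kept"` or `"ratio"`).
#' @export
quack_filter <- function(pct, experimental_ids, blank_ids, factor = 5) {
  if (length(intersect(experimental_ids, blank_ids))) {
    stop("experimental and blank sample sets overlap")
  }
  experimental_ids <- intersect(experimental_ids, colnames(pct))
  blank_ids <- intersect(blank_ids, colnames(pct))
  max_e <- if (length(experimental_ids)) {
    apply(pct[, experimental_ids, drop = FALSE], 1, max)
  } else rep(0, nrow(pct))
  if (!length(blank_ids)) {
    warning("no blank samples supplied: contamination rule not applied, ",
            "all ZOTUs kept")
    max_b <- rep(0, nrow(pct))
    keep <- max_e > 0
  } else {
    max_b <- apply(pct[, blank_ids, drop = FALSE], 1, max)
    keep <- max_e > 0 & max_e >= factor * max_b
  }
  data.frame(
    zotu_id = rownames(pct), max_sample_pct = max_e, max_blank_pct = max_b,
    keep = keep, reason = ifelse(keep, "kept", "ratio"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Remove non-target taxa and chimeras
#'
#' Drops ZOTUs classified as Archaea or Eukaryota at the domain rank, as
#' chloroplast or mitochondria at any rank, and flagged chimeras.
#'
#' @param counts ZOTU x sample matrix.
#' @param taxonomy data.frame with rank columns (as [parse_tax_headers()])
#'   rows matching `rownames(counts)`.
#' @param chimera Logical chimera flags per ZOTU (default none).
#' @return list: `counts` (filtered), `removed` (named character: reason per
#'   removed ZOTU id).
#' @export
remove_nontarget <- function(counts, taxonomy, chimera = rep(FALSE, nrow(counts))) {
  reason <- rep(NA_character_, nrow(counts))
  dom <- taxonomy$domain
  reason[!is.na(dom) & dom == "Archaea"] <- "archaea"
  reason[!is.na(dom) & dom == "Eukaryota"] <- "eukaryota"
  rank_mat <- as.matrix(taxonomy[, intersect(TAX_RANKS, names(taxonomy)), drop = FALSE])
  has <- function(what) {
    apply(rank_mat, 1, function(r) any(!is.na(r) & tolower(r) == what))
  }
  reason[is.na(reason) & has("chloroplast")] <- "chloroplast"
  reason[is.na(reason) & has("mitochondria")] <- "mitochondria"
  reason[is.na(reason) & chimera] <- "chimera"
  drop <- !is.na(reason)
  list(counts = counts[!drop, , drop = FALSE],
       removed = stats::setNames(reason[drop], rownames(counts)[drop]))
}

#' Separate spike-in reads from a ZOTU table
#'
#' ZOTUs matching a spike-in reference at >= `min_identity` are tabulated
#' per sample and removed from the table. The extraction spike-in drives
#' quantification; a PCR spike-in reference, if supplied, is detected and
#' dropped without use.
#'
#' @param counts ZOTU x sample matrix.
#' @param seqs ZOTU sequences (rows of `counts`).
#' @param spike_seqs Named character: spike-in reference sequence(s).
#' @param min_identity Identity for spike-in recognition.
#' @return list: `counts` (without spike-in rows), `spike_reads` (named
#'   numeric per sample, summed over matching ZOTUs of the first reference),
#'   `spike_zotus` (named character: matched reference per spike ZOTU).
#' @export
split_spikein <- function(counts, seqs, spike_seqs, min_identity = 0.99) {
  hits <- rep(NA_character_, nrow(counts))
  for (nm in names(spike_seqs)) {
    len_ok <- abs(nchar(seqs) - nchar(spike_seqs[[nm]])) <= 5
    if (!any(len_ok)) next
    ids <- seq_identity(seqs[len_ok], spike_seqs[[nm]])
    hit <- which(len_ok)[ids >= min_identity]
    hits[hit] <- nm
  }
  main <- names(spike_seqs)[1]
  spike_rows <- which(hits == main)
  spike_reads <- if (length(spike_rows)) {
    colSums(counts[spike_rows, , drop = FALSE])
  } else stats::setNames(rep(0, ncol(counts)), colnames(counts))
  list(counts = counts[is.na(hits), , drop = FALSE],
       spike_reads = spike_reads,
       spike_zotus = stats::setNames(hits[!is.na(hits)],
                                     rownames(counts)[!is.na(hits)]))
}
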