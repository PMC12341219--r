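# Wolbachia bycatch from COI amplicons: strain tables, presence calls, and
# cross-marker concordance against 16S.

#' Extract the Wolbachia strain table from COI ZOTUs
#'
#' Takes the Rickettsiales subset of a COI ZOTU table and retains only
#' ZOTUs classified as Wolbachia, of exactly `required_len` nucleotides,
#' and not flagged chimeric.
#'
#' @param counts COI ZOTU x sample matrix.
#' @param seqs ZOTU sequences (rows of `counts`).
#' @param taxonomy Rank data.frame rows matching `counts`.
#' @param chimera Logical chimera flags.
#' @param required_len Required sequence length.
#' @return list: `counts` (Wolbachia ZOTU x sample), `seqs`,
#'   `rickettsiales_counts` (the order-level subset before strain filters).
#' @export
extract_wolbachia <- function(counts, seqs, taxonomy,
                              chimera = rep(FALSE, nrow(counts)),
                              required_len = 418L) {
  ord <- taxonomy$order
  rick <- !is.na(ord) & ord == "Rickettsiales"
  gen <- taxonomy$genus
  keep <- rick & !is.na(gen) & gen == "Wolbachia" &
    nchar(seqs) == required_len & !chimera
  list(counts = counts[keep, , drop = FALSE],
       seqs = seqs[keep],
       rickettsiales_counts = counts[rick, , drop = FALSE])
}

#' Per-sample presence calls from read sums
#'
#' A sample scores present when its summed reads reach `min_reads`
#' (inclusive).
#'
#' @param counts Taxa x sample matrix.
#' @param min_reads Presence threshold.
#' @return Named logical vector per sample.
#' @export
call_presence <- function(counts, min_reads = 2L) {
  colSums(counts) >= min_reads
}

#' Cross-marker agreement of presence calls
#'
#' Compares COI- and 16S-based Wolbachia presence over the same samples.
#' Returns simple concordance (both present + both absent over n), the 2x2
#' contingency table, and Cohen's kappa.
#'
#' @param coi_presence,s16_presence Named logical vectors over the same
#'   sample universe.
#' @return list: `agreement`, `table`, `kappa`, `n`.
#' @export
cross_marker_agreement <- function(coi_presence, s16_presence) {
  common <- intersect(names(coi_presence), names(s16_presence))
  if (!length(common)) stop("disjoint sample sets")
  a <- coi_presence[common]
  b <- s16_presence[common]
  tab <- table(factor(a, c(FALSE, TRUE), c("absent", "present")),
               factor(b, c(FALSE, TRUE), c("absent", "present")),
               dnn = c("COI", "16S"))
  n <- length(common)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  list(agreement = po, table = tab, kappa = kappa, n = n)
}
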