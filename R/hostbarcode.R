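# Host COI barcode designation, per-sample QC, species-cluster proposal
# against reference barcodes, name assignment, and the sex-ratio test.

#' Designate one sample's COI barcode
#'
#' After COI decontamination (length-418, arthropod-classified, non-chimeric
#' sequences only), the dominant OTU is the arthropod OTU with most reads in
#' the sample; its read ratio is taken relative to all arthropod reads. The
#' sample passes when the dominant OTU has at least `min_dominant_reads`
#' reads and the ratio is at least `min_ratio`; its barcode is the most
#' abundant ZOTU sequence within the dominant OTU.
#'
#' @param counts Named integer vector: reads per COI ZOTU for this sample
#'   (arthropod, 418-nt, non-chimeric ZOTUs only).
#' @param otu Integer OTU index per ZOTU (parallel to `counts`).
#' @param seqs Character: ZOTU sequences (parallel to `counts`).
#' @param min_dominant_reads Minimum dominant-OTU read count (inclusive).
#' @param min_ratio Minimum dominant/total arthropod read ratio (inclusive).
#' @return list: `pass`, `barcode_seq`, `dominant_otu_reads`,
#'   `arthropod_ratio`, `reject_reason` (NA when passing).
#' @export
select_barcode <- function(counts, otu, seqs, min_dominant_reads = 300L,
                           min_ratio = 0.95) {
  total <- sum(counts)
  if (total == 0) {
    return(list(pass = FALSE, barcode_seq = NA_character_,
                dominant_otu_reads = 0L, arthropod_ratio = NA_real_,
                reject_reason = "no_barcode"))
  }
  by_otu <- tapply(counts, otu, sum)
  dom <- names(by_otu)[which.max(by_otu)]
  dom_reads <- as.integer(by_otu[[dom]])
  ratio <- dom_reads / total
  in_dom <- otu == as.integer(dom)
  barcode <- seqs[in_dom][which.max(counts[in_dom])]
  pass <- dom_reads >= min_dominant_reads && ratio >= min_ratio
  reason <- if (pass) NA_character_
  else if (dom_reads < min_dominant_reads) "low_reads" else "low_ratio"
  list(pass = pass, barcode_seq = unname(barcode),
       dominant_otu_reads = dom_reads, arthropod_ratio = ratio,
       reject_reason = reason)
}

# pairwise p-distance matrix for equal-length barcodes; positions with N are
# dropped per pair; pairs overlapping on < (1 - max_n_frac) of sites get NA
barcode_pdist <- function(seqs, max_n_frac = 0.10) {
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  L <- nchar(seqs[1])
  nN <- vapply(seqs, function(s) sum(strsplit(s, "")[[1]] == "N"), numeric(1))
  bad <- outer(nN, nN, "+") / L > max_n_frac
  d[bad] <- NA
  d
}

#' Propose species-level clusters of barcode genotypes
#'
#' Average-linkage hierarchical clustering on pairwise p-distance over the
#' genotypes plus named reference barcodes, cut at `cut` (3% by default).
#' Clusters joining references of more than one named species are flagged
#' ambiguous, standing in for manual dendrogram review.
#'
#' @param genotype_seqs Named character vector of dereplicated barcodes.
#' @param ref_seqs Named character vector of reference barcodes.
#' @param ref_species Character: species name per reference.
#' @param cut Height (p-distance) at which the dendrogram is cut.
#' @return list: `cluster` (integer per genotype), `ambiguous` (logical per
#'   cluster), `cluster_species` (list of reference species per cluster),
#'   `hclust` (the dendrogram object).
#' @export
propose_species_clusters <- function(genotype_seqs, ref_seqs = character(0),
                                     ref_species = character(0), cut = 0.03) {
  all_seqs <- c(genotype_seqs, ref_seqs)
  is_ref <- c(rep(FALSE, length(genotype_seqs)), rep(TRUE, length(ref_seqs)))
  d <- barcode_pdist(all_seqs)
  d[is.na(d)] <- max(d, 1, na.rm = TRUE) + 1  # excluded pairs never cluster
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, h = cut)
  # renumber clusters over genotypes only, by first occurrence
  gt_grp <- grp[!is_ref]
  ids <- match(gt_grp, unique(gt_grp))
  cluster_species <- lapply(unique(gt_grp), function(g) {
    unique(ref_species[grp[is_ref] == g])
  })
  ambiguous <- vapply(cluster_species, function(s) length(s) > 1L, logical(1))
  list(cluster = stats::setNames(ids, names(genotype_seqs)),
       ambiguous = ambiguous, cluster_species = cluster_species, hclust = hc)
}

#' Assign a name to a barcode genotype
#'
#' The species name of the best-matching named reference is assigned when
#' identity is at least `min_identity`; otherwise the classifier's genus-
#' (or family-) level label is used as fallback.
#'
#' @param seq Genotype barcode sequence.
#' @param ref_seqs Named reference barcodes.
#' @param ref_species Species name per reference.
#' @param fallback Named character from a taxonomy classifier (e.g. the
#'   `labels` of [classify_taxonomy()]) supplying `genus`/`family`.
#' @param min_identity Identity required for a species-level name.
#' @return list: `name`, `level` (`"species"`, `"genus"`, `"family"` or
#'   `"unassigned"`), `identity` to the best reference (NA without refs).
#' @export
assign_name <- function(seq, ref_seqs, ref_species,
                        fallback = character(0), min_identity = 0.97) {
  fall <- function() {
    for (lv in c("genus", "family")) {
      if (lv %in% names(fallback)) {
        return(list(name = unname(fallback[[lv]]), level = lv, identity = NA_real_))
      }
    }
    list(name = NA_character_, level = "unassigned", identity = NA_real_)
  }
  if (!length(ref_seqs)) return(fall())
  ids <- seq_identity(ref_seqs, seq)
  best <- which.max(ids)
  if (ids[best] >= min_identity) {
    list(name = ref_species[best], level = "species", identity = ids[best])
  } else {
    out <- fall()
    out$identity <- ids[best]
    out
  }
}

#' Chi-squared test of a 1:1 sex ratio
#'
#' One-degree-of-freedom goodness-of-fit statistic
#' \eqn{\sum (O - E)^2 / E} with \eqn{E = n/2}.
#'
#' @param n_female,n_male Observed counts.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
sex_ratio_test <- function(n_female, n_male) {
  n <- n_female + n_male
  if (n <= 0) stop("no individuals")
  e <- n / 2
  stat <- (n_female - e)^2 / e + (n_male - e)^2 / e
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Rank-abundance species numbering
#'
#' Species receive `"sp. 1"`, `"sp. 2"`, ... by descending individual
#' counts; ties by first occurrence.
#'
#' @param species_per_sample Character/integer vector: species cluster of
#'   each individual.
#' @return Named character: `"sp. k"` label per distinct species, in input
#'   cluster units.
#' @export
species_rank_labels <- function(species_per_sample) {
  tb <- table(factor(species_per_sample,
                     levels = unique(as.character(species_per_sample))))
  ord <- order(-as.integer(tb))  # stable: ties keep first-occurrence order
  stats::setNames(paste0("sp. ", order(ord)), names(tb))
}
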