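# Per-library denoising into ZOTUs, chimera flagging, greedy 97% OTU
# clustering across samples, and k-mer bootstrap taxonomy.

#' Dereplicate a library's contigs
#'
#' Groups exact-identical sequences and drops those below `min_count`
#' (singletons by default).
#'
#' @param seqs Character vector of QC-passed contig sequences.
#' @param min_count Minimum occurrence count retained.
#' @return data.frame with `seq` and `count`, sorted by descending count
#'   (ties broken lexicographically by sequence for determinism).
#' @export
dereplicate <- function(seqs, min_count = 2L) {
  if (!length(seqs)) {
    warning("empty library")
    return(data.frame(seq = character(0), count = integer(0)))
  }
  tb <- table(seqs)
  out <- data.frame(seq = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[out$count >= min_count, , drop = FALSE]
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' UNOISE abundance-skew threshold
#'
#' beta(d) = 1 / 2^(alpha*d + 1): the maximum abundance ratio at which a
#' sequence at edit distance d from a centroid is absorbed as an error
#' variant of that centroid.
#'
#' @param d Edit distance (>= 1).
#' @param alpha Skew steepness.
#' @return Numeric threshold.
#' @export
unoise_beta <- function(d, alpha = 2) {
  1 / 2^(alpha * d + 1)
}

#' UNOISE-style denoising of one library
#'
#' Greedy pass over unique sequences in descending count order: each
#' candidate joins the first accepted centroid C (in acceptance order) with
#' edit distance `d >= 1` satisfying `count/count(C) <= unoise_beta(d,
#' alpha)`; otherwise it founds a new centroid if its count reaches
#' `minsize`.
#'
#' @param uniques data.frame from [dereplicate()] (descending count order).
#' @param alpha Skew steepness of the merge curve.
#' @param minsize Minimum count to found a centroid.
#' @return list with `zotus` (data.frame `seq`, `count` where `count`
#'   accumulates member counts) and `members` (integer vector mapping each
#'   input unique to its centroid's row, NA if discarded).
#' @export
unoise_denoise <- function(uniques, alpha = 2, minsize = 2L) {
  n <- nrow(uniques)
  members <- rep(NA_integer_, n)
  cent_idx <- integer(0)       # rows of `uniques` that became centroids
  cent_count <- integer(0)     # original (unique) count of each centroid
  acc_count <- numeric(0)      # accumulated member counts
  beta1 <- unoise_beta(1, alpha)
  for (i in seq_len(n)) {
    ct <- uniques$count[i]
    joined <- FALSE
    for (k in seq_along(cent_idx)) {
      if (ct / cent_count[k] > beta1) next   # beta decreasing in d: hopeless
      d <- utils::adist(uniques$seq[i], uniques$seq[cent_idx[k]])[1, 1]
      if (d >= 1 && ct / cent_count[k] <= unoise_beta(d, alpha)) {
        members[i] <- k
        acc_count[k] <- acc_count[k] + ct
        joined <- TRUE
        break
      }
    }
    if (!joined && ct >= minsize) {
      cent_idx <- c(cent_idx, i)
      cent_count <- c(cent_count, ct)
      acc_count <- c(acc_count, ct)
      members[i] <- length(cent_idx)
    }
  }
  list(
    zotus = data.frame(seq = uniques$seq[cent_idx], count = acc_count,
                       stringsAsFactors = FALSE),
    members = members
  )
}

# longest common prefix length of `seq` vs each of `others` (same alphabet)
lcp_len <- function(seq, others) {
  a <- utf8ToInt(seq)
  vapply(others, function(s) {
    b <- utf8ToInt(s)
    m <- min(length(a), length(b))
    neq <- which(a[seq_len(m)] != b[seq_len(m)])
    if (length(neq)) neq[1] - 1L else m
  }, integer(1), USE.NAMES = FALSE)
}

#' Flag candidate chimeras among ZOTUs
#'
#' Simplified exact two-parent test: a ZOTU is flagged when, for some
#' breakpoint, its left segment exactly matches the prefix of one parent
#' and its right segment exactly matches the (end-aligned) suffix of a
#' different parent, with each parent at least `parent_fold` times as
#' abundant, and no single parent matching it full length.
#'
#' @param zotus data.frame with `seq` and `count`.
#' @param parent_fold Minimum parent/candidate abundance ratio.
#' @return Logical vector of chimera flags.
#' @export
flag_chimeras <- function(zotus, parent_fold = 2) {
  n <- nrow(zotus)
  flags <- logical(n)
  if (n < 3L) return(flags)
  rev_seqs <- vapply(zotus$seq, function(s) intToUtf8(rev(utf8ToInt(s))),
                     character(1), USE.NAMES = FALSE)
  for (i in seq_len(n)) {
    par <- which(zotus$count >= parent_fold * zotus$count[i])
    par <- setdiff(par, i)
    if (length(par) < 2L) next
    len <- nchar(zotus$seq[i])
    lcp <- lcp_len(zotus$seq[i], zotus$seq[par])
    lcs <- lcp_len(rev_seqs[i], rev_seqs[par])
    full <- lcp == len & nchar(zotus$seq[par]) == len
    if (any(full)) next                         # exact duplicate of a parent
    lcp <- pmin(lcp, len - 1L)                  # both segments non-empty
    lcs <- pmin(lcs, len - 1L)
    # need distinct parents A,B with lcp(A) + lcs(B) >= len; for each A the
    # best partner is the max lcs excluding A itself (top-2 trick)
    j1 <- which.max(lcs)
    lcs2 <- lcs; lcs2[j1] <- -1L
    j2 <- which.max(lcs2)
    partner <- ifelse(seq_along(lcs) == j1, lcs[j2], lcs[j1])
    if (any(lcp + partner >= len)) flags[i] <- TRUE
  }
  flags
}

#' Pairwise identity from a unit-cost global alignment
#'
#' Identity is matches / alignment columns of a global alignment with unit
#' edit costs and penalised end gaps. With substitutions S, insertions I
#' and deletions D on the optimal edit path from query (length n) to
#' subject, matches are n - S - D and alignment columns n + I.
#'
#' @param query Character vector of sequences.
#' @param subject A single subject sequence.
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
seq_identity <- function(query, subject) {
  d <- utils::adist(query, subject, counts = TRUE)
  cts <- attr(d, "counts")
  ins <- cts[, 1, "ins"]
  del <- cts[, 1, "del"]
  sub <- cts[, 1, "sub"]
  n <- nchar(query)
  (n - sub - del) / (n + ins)
}

#' Greedy centroid clustering of ZOTUs into OTUs
#'
#' ZOTUs are visited in descending total-count order (ties lexicographic);
#' each joins the first existing centroid (in creation order, i.e. highest
#' abundance first) at identity >= `identity`, else founds a new OTU.
#'
#' @param seqs ZOTU centroid sequences.
#' @param counts Total counts (across samples) per ZOTU.
#' @param identity Identity cutoff.
#' @return list with `otu` (integer OTU index per input ZOTU) and
#'   `centroid` (input index of each OTU's centroid).
#' @export
cluster_otus <- function(seqs, counts, identity = 0.97) {
  ord <- order(-counts, seqs)
  otu <- integer(length(seqs))
  centroids <- integer(0)
  for (i in ord) {
    placed <- FALSE
    if (length(centroids)) {
      ids <- seq_identity(seqs[centroids], seqs[i])
      hit <- which(ids >= identity)
      if (length(hit)) {
        otu[i] <- hit[1]
        placed <- TRUE
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      otu[i] <- length(centroids)
    }
  }
  list(otu = otu, centroid = centroids)
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Parse `tax=` annotations from reference FASTA headers
#'
#' Headers carry `tax=d:...,p:...,c:...,o:...,f:...,g:...,s:...` (ranks may
#' be truncated from the right).
#'
#' @param headers Character vector of FASTA header lines (without `>`).
#' @return data.frame with one column per rank (NA where absent) plus `id`.
#' @export
parse_tax_headers <- function(headers) {
  keys <- c(d = "domain", p = "phylum", c = "class", o = "order",
            f = "family", g = "genus", s = "species")
  out <- data.frame(id = sub("\\s.*$", "", headers), stringsAsFactors = FALSE)
  for (r in TAX_RANKS) out[[r]] <- NA_character_
  tax <- sub("^.*tax=", "", headers)
  fields <- strsplit(tax, ",")
  for (i in seq_along(fields)) {
    for (f in fields[[i]]) {
      kv <- strsplit(f, ":")[[1]]
      if (length(kv) == 2 && kv[1] %in% names(keys)) {
        out[i, keys[[kv[1]]]] <- kv[2]
      }
    }
  }
  out
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' k-mer bootstrap taxonomy classifier
#'
#' SINTAX-style: each bootstrap draws `subsample` k-mers with replacement
#' from the query's k-mer set and votes for the reference sharing most of
#' them (ties broken at random, seeded). Per-rank confidence is the vote
#' fraction for the winning lineage's label at that rank; the reported
#' lineage is truncated at the deepest rank with confidence >= `cutoff`.
#'
#' @param seq Query sequence.
#' @param ref_seqs Named character vector of reference sequences.
#' @param ref_tax data.frame from [parse_tax_headers()], rows matching
#'   `ref_seqs`.
#' @param n_boot Bootstrap replicates.
#' @param kmer k-mer length.
#' @param subsample k-mers drawn per bootstrap.
#' @param cutoff Confidence cutoff for the reported rank.
#' @param seed Integer seed for the bootstrap stream.
#' @return list with `labels` (named character, reported ranks only),
#'   `confidence` (named numeric over all ranks of the winning lineage) and
#'   `classified` (logical).
#' @export
classify_taxonomy <- function(seq, ref_seqs, ref_tax, n_boot = 100L,
                              kmer = 8L, subsample = 32L, cutoff = 0.80,
                              seed = 1L) {
  stopifnot(length(ref_seqs) > 0)
  qk <- kmer_set(seq, kmer)
  if (!length(qk)) {
    return(list(labels = character(0), confidence = numeric(0), classified = FALSE))
  }
  rk <- lapply(ref_seqs, kmer_set, k = kmer)
  votes <- with_seed(seed, {
    v <- integer(n_boot)
    for (b in seq_len(n_boot)) {
      draw <- qk[sample.int(length(qk), subsample, replace = TRUE)]
      shared <- vapply(rk, function(s) sum(draw %in% s), integer(1))
      if (max(shared) == 0L) {
        v[b] <- NA_integer_
      } else {
        top <- which(shared == max(shared))
        v[b] <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
      }
    }
    v
  })
  if (all(is.na(votes))) {
    return(list(labels = character(0), confidence = numeric(0), classified = FALSE))
  }
  win <- as.integer(names(which.max(table(votes))))
  conf <- numeric(0)
  for (r in TAX_RANKS) {
    lab <- ref_tax[[r]][win]
    if (is.na(lab)) break
    same <- ref_tax[[r]][votes] == lab
    same[is.na(same)] <- FALSE
    conf[[r]] <- sum(same) / n_boot
  }
  # enforce monotone non-increasing confidence down the ranks
  if (length(conf) > 1) conf <- cummin(conf)
  keep <- conf >= cutoff
  deepest <- if (any(keep)) max(which(keep)) else 0L
  labels <- if (deepest > 0) {
    stats::setNames(
      vapply(names(conf)[seq_len(deepest)], function(r) ref_tax[[r]][win], character(1)),
      names(conf)[seq_len(deepest)]
    )
  } else character(0)
  list(labels = labels, confidence = conf, classified = deepest > 0L)
}

#' Build a ZOTU-by-sample table from per-library denoising results
#'
#' ZOTU identity across samples is established by exact sequence match of
#' the per-library centroids.
#'
#' @param per_sample Named list (by sample id) of `zotus` data.frames from
#'   [unoise_denoise()].
#' @return list with `counts` (ZOTU x sample integer matrix), `seqs`
#'   (centroid sequence per row) and `zotu_id` (row names `ZOTU1..`,
#'   numbered by descending total count).
#' @export
build_zotu_table <- function(per_sample) {
  all_seqs <- unique(unlist(lapply(per_sample, `[[`, "seq"), use.names = FALSE))
  counts <- matrix(0L, length(all_seqs), length(per_sample),
                   dimnames = list(NULL, names(per_sample)))
  for (s in names(per_sample)) {
    z <- per_sample[[s]]
    if (nrow(z)) counts[match(z$seq, all_seqs), s] <- as.integer(round(z$count))
  }
  ord <- order(-rowSums(counts), all_seqs)
  counts <- counts[ord, , drop = FALSE]
  seqs <- all_seqs[ord]
  ids <- paste0("ZOTU", seq_along(seqs))
  rownames(counts) <- ids
  list(counts = counts, seqs = stats::setNames(seqs, ids), zotu_id = ids)
}
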