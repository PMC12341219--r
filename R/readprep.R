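# Read preparation: primer-based target splitting, pair merging, QC filters.
#
# Mixed libraries carry both host COI (BF3/BR2) and bacterial 16S-V4
# (515F/806R) amplicons, with short variable-length heterogeneity spacers
# between the adapter stub and the primer. Reads are assigned to a target
# when both mates match that target's primers, then primer+spacer are
# trimmed, pairs merged into contigs, and contigs filtered by the expected
# length window and by low-quality runs.

#' Default primer schemes for the mixed COI + 16S-V4 design
#'
#' 515F/806R for the 16S-V4 target and BF3/BR2 for the COI target, with a
#' heterogeneity-spacer search window and a per-primer mismatch tolerance.
#'
#' @param max_spacer Maximum spacer length searched before the primer.
#' @param max_mismatches Mismatches tolerated per primer.
#' @return A list of primer scheme lists with elements `target_id`,
#'   `fwd_primer`, `rev_primer`, `max_spacer_len`, `max_mismatches`.
#' @export
default_primer_schemes <- function(max_spacer = 7L, max_mismatches = 1L) {
  list(
    list(target_id = "16S", fwd_primer = "GTGYCAGCMGCCGCGGTAA",
         rev_primer = "GGACTACNVGGGTWTCTAAT",
         max_spacer_len = max_spacer, max_mismatches = max_mismatches),
    list(target_id = "COI", fwd_primer = "CCHGAYATRGCHTTYCCHCG",
         rev_primer = "TCDGGRTGNCCRAARAAYCA",
         max_spacer_len = max_spacer, max_mismatches = max_mismatches)
  )
}

check_iupac <- function(primer) {
  bases <- strsplit(primer, "")[[1]]
  bad <- setdiff(bases, names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC code(s) in primer: ", paste(bad, collapse = ", "))
  }
  bases
}

# Mismatch counts of `primer` against `seqs` at offsets 0..max_spacer.
# Returns an integer matrix [length(seqs) x (max_spacer+1)]; NA where the
# sequence is too short for that offset.
primer_mismatch_profile <- function(seqs, primer, max_spacer) {
  bases <- check_iupac(primer)
  L <- length(bases)
  n <- length(seqs)
  out <- matrix(NA_integer_, n, max_spacer + 1L)
  len <- nchar(seqs)
  for (off in 0:max_spacer) {
    ok <- len >= off + L
    if (!any(ok)) next
    mm <- integer(sum(ok))
    for (j in seq_len(L)) {
      ch <- substring(seqs[ok], off + j, off + j)
      mm <- mm + !(ch %in% IUPAC_SETS[[bases[j]]])
    }
    out[ok, off + 1L] <- mm
  }
  out
}

#' Locate a primer near the start of a sequence
#'
#' Searches offsets `0..max_spacer` for an IUPAC-compatible primer match
#' with at most `max_mm` mismatches. Among qualifying offsets the one with
#' fewest mismatches wins; ties go to the smaller offset.
#'
#' @param seq A single DNA string.
#' @param primer IUPAC primer string.
#' @param max_spacer Largest spacer length searched before the primer.
#' @param max_mm Maximum mismatches tolerated.
#' @return `list(offset=, mismatches=)` or `NULL` if no match.
#' @export
match_primer <- function(seq, primer, max_spacer = 7L, max_mm = 1L) {
  prof <- primer_mismatch_profile(seq, primer, max_spacer)[1, ]
  cand <- which(!is.na(prof) & prof <= max_mm)
  if (!length(cand)) return(NULL)
  best <- cand[which.min(prof[cand])]
  list(offset = best - 1L, mismatches = as.integer(prof[best]))
}

# vectorised best offset per read: list(offset, mm) with NA for no match
best_primer_hits <- function(seqs, primer, max_spacer, max_mm) {
  prof <- primer_mismatch_profile(seqs, primer, max_spacer)
  prof[is.na(prof)] <- .Machine$integer.max
  mm <- apply(prof, 1L, min)
  # smallest offset among minima (max.col with ties.method="first" on -prof)
  off <- max.col(-prof, ties.method = "first") - 1L
  hit <- mm <= max_mm
  list(offset = ifelse(hit, off, NA_integer_),
       mismatches = ifelse(hit, mm, NA_integer_))
}

trim_at <- function(seqs, quals, offsets, primer_len) {
  start <- offsets + primer_len + 1L
  list(seq = substring(seqs, start), qual = substring(quals, start))
}

#' Split a mixed paired library by amplicon target
#'
#' Each pair is assigned to the single scheme whose forward primer matches
#' the forward read and whose reverse primer matches the reverse read;
#' primers and spacers are trimmed. Pairs whose mates match different
#' targets, or no target, go to the unassigned bin. A rescue pass with
#' swapped mate roles (reverse primer on R1) is attempted before a pair is
#' declared unassigned.
#'
#' @param pairs Read-pair data.frame (see [read_fastq_pairs()]).
#' @param schemes List of primer schemes ([default_primer_schemes()]).
#' @return A list with `targets` (named list of trimmed read-pair
#'   data.frames), `unassigned` (data.frame), and `counts` (named integer
#'   vector incl. `unassigned`).
#' @export
split_reads <- function(pairs, schemes = default_primer_schemes()) {
  n <- nrow(pairs)
  tnames <- vapply(schemes, `[[`, character(1), "target_id")
  assign <- rep(NA_integer_, n)
  swapped <- rep(FALSE, n)
  offF <- offR <- rep(NA_integer_, n)
  for (orient in c("direct", "swapped")) {
    open <- is.na(assign)
    if (!any(open)) break
    fs <- if (orient == "direct") pairs$fwd_seq[open] else pairs$rev_seq[open]
    rs <- if (orient == "direct") pairs$rev_seq[open] else pairs$fwd_seq[open]
    hitF <- hitR <- matrix(NA_integer_, sum(open), length(schemes))
    for (k in seq_along(schemes)) {
      sc <- schemes[[k]]
      hf <- best_primer_hits(fs, sc$fwd_primer, sc$max_spacer_len, sc$max_mismatches)
      hr <- best_primer_hits(rs, sc$rev_primer, sc$max_spacer_len, sc$max_mismatches)
      hitF[, k] <- hf$offset
      hitR[, k] <- hr$offset
    }
    both <- !is.na(hitF) & !is.na(hitR)
    nhit <- rowSums(both)
    take <- nhit == 1L            # ambiguous (both targets) stays unassigned
    if (any(take)) {
      k <- max.col(both, ties.method = "first")
      idx <- which(open)[take]
      assign[idx] <- k[take]
      swapped[idx] <- orient == "swapped"
      offF[idx] <- hitF[cbind(which(take), k[take])]
      offR[idx] <- hitR[cbind(which(take), k[take])]
    }
  }
  targets <- list()
  for (k in seq_along(schemes)) {
    sc <- schemes[[k]]
    sel <- which(assign == k)
    if (!length(sel)) {
      targets[[sc$target_id]] <- pairs[0, , drop = FALSE]
      next
    }
    fseq <- ifelse(swapped[sel], pairs$rev_seq[sel], pairs$fwd_seq[sel])
    fq   <- ifelse(swapped[sel], pairs$rev_qual[sel], pairs$fwd_qual[sel])
    rseq <- ifelse(swapped[sel], pairs$fwd_seq[sel], pairs$rev_seq[sel])
    rq   <- ifelse(swapped[sel], pairs$fwd_qual[sel], pairs$rev_qual[sel])
    tf <- trim_at(fseq, fq, offF[sel], nchar(sc$fwd_primer))
    tr <- trim_at(rseq, rq, offR[sel], nchar(sc$rev_primer))
    targets[[sc$target_id]] <- data.frame(
      read_id = pairs$read_id[sel],
      fwd_seq = tf$seq, rev_seq = tr$seq,
      fwd_qual = tf$qual, rev_qual = tr$qual,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  unassigned <- pairs[is.na(assign), , drop = FALSE]
  counts <- c(vapply(targets, nrow, integer(1)), unassigned = nrow(unassigned))
  list(targets = targets, unassigned = unassigned, counts = counts)
}

#' Merge one primer-trimmed read pair into a contig
#'
#' Scans ungapped overlaps of the reverse-complemented reverse read against
#' the forward read, scoring matches minus mismatches, and keeps the best
#' (ties go to the longer overlap). At overlap mismatches the
#' higher-quality base wins; at matches the consensus quality is the larger
#' of the two.
#'
#' @param fwd_seq,rev_seq Forward read and (as-sequenced) reverse read.
#' @param fwd_qual,rev_qual Phred+33 quality strings.
#' @param min_overlap Minimum acceptable overlap length.
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap.
#' @return `list(seq=, qual=, overlap_len=)` or `NULL` when rejected.
#' @export
merge_pair <- function(fwd_seq, rev_seq, fwd_qual, rev_qual,
                       min_overlap = 20L, max_mismatch_frac = 0.25) {
  rc <- revcomp(rev_seq)
  rq <- intToUtf8(rev(utf8ToInt(rev_qual)))
  f <- utf8ToInt(fwd_seq); r <- utf8ToInt(rc)
  fq <- utf8ToInt(fwd_qual) - 33L; rqv <- utf8ToInt(rq) - 33L
  nf <- length(f); nr <- length(r)
  if (nf < min_overlap || nr < min_overlap) return(NULL)
  best <- NULL; best_score <- -Inf
  for (o in min(nf, nr):min_overlap) {
    fi <- (nf - o + 1L):nf
    ri <- 1L:o
    mism <- sum(f[fi] != r[ri])
    score <- o - 2L * mism
    if (score > best_score) {
      best_score <- score
      best <- list(o = o, mism = mism, fi = fi, ri = ri)
    }
  }
  if (is.null(best) || best$mism / best$o > max_mismatch_frac) return(NULL)
  o <- best$o
  cons <- r[best$ri]
  consq <- pmax(fq[best$fi], rqv[best$ri])
  use_f <- f[best$fi] == cons | fq[best$fi] >= rqv[best$ri]
  cons[use_f] <- f[best$fi][use_f]
  tail_i <- if (o < nr) (o + 1L):nr else integer(0)
  seq <- intToUtf8(c(f[seq_len(nf - o)], cons, r[tail_i]))
  qual <- intToUtf8(c(fq[seq_len(nf - o)], consq, rqv[tail_i]) + 33L)
  list(seq = seq, qual = qual, overlap_len = o)
}

#' Merge all pairs of a library
#'
#' Identical read pairs are merged once and the result replicated, which
#' makes error-free simulated libraries cheap.
#'
#' @param pairs Primer-trimmed read-pair data.frame.
#' @inheritParams merge_pair
#' @return data.frame with `read_id`, `seq`, `qual`, `overlap_len` for
#'   merged pairs only; attribute `n_rejected` carries the reject count.
#' @export
merge_pairs <- function(pairs, min_overlap = 20L, max_mismatch_frac = 0.25) {
  if (!nrow(pairs)) {
    out <- data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), overlap_len = integer(0))
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  key <- paste(pairs$fwd_seq, pairs$rev_seq, pairs$fwd_qual, pairs$rev_qual, sep = "\r")
  uk <- !duplicated(key)
  merged <- vector("list", sum(uk))
  ui <- which(uk)
  for (i in seq_along(ui)) {
    p <- pairs[ui[i], ]
    merged[[i]] <- merge_pair(p$fwd_seq, p$rev_seq, p$fwd_qual, p$rev_qual,
                              min_overlap, max_mismatch_frac)
  }
  names(merged) <- key[ui]
  res <- merged[key]
  keep <- !vapply(res, is.null, logical(1))
  out <- data.frame(
    read_id = pairs$read_id[keep],
    seq = vapply(res[keep], `[[`, character(1), "seq"),
    qual = vapply(res[keep], `[[`, character(1), "qual"),
    overlap_len = vapply(res[keep], `[[`, integer(1), "overlap_len"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Target length windows for merged contigs
#' @return Named list of `c(min, max)` contig lengths per target.
#' @export
target_length_windows <- function() {
  list(COI = c(400L, 430L), `16S` = c(250L, 260L))
}

#' Quality/length filter for merged contigs
#'
#' A contig is rejected if its length falls outside the target's expected
#' window (400-430 nt for COI, 250-260 nt for 16S-V4) or if it contains a
#' low-quality region, operationalised as a run of at least `run_len`
#' consecutive bases with Phred score at or below `q_thresh`.
#'
#' @param contigs data.frame with `seq` and `qual` columns.
#' @param target_id `"COI"` or `"16S"`.
#' @param q_thresh Phred threshold defining a low-quality base.
#' @param run_len Run length of low-quality bases triggering rejection.
#' @param windows Length windows, see [target_length_windows()].
#' @return Input rows that pass, with attribute `rejects` (a factor of
#'   reasons, `"length"` or `"quality"`, one per rejected contig).
#' @export
qc_filter <- function(contigs, target_id, q_thresh = 30L, run_len = 3L,
                      windows = target_length_windows()) {
  if (!target_id %in% names(windows)) {
    stop("unknown target_id: ", target_id)
  }
  w <- windows[[target_id]]
  len_ok <- nchar(contigs$seq) >= w[1] & nchar(contigs$seq) <= w[2]
  qual_bad <- vapply(contigs$qual, function(qs) {
    q <- utf8ToInt(qs) - 33L
    r <- rle(q <= q_thresh)
    any(r$values & r$lengths >= run_len)
  }, logical(1), USE.NAMES = FALSE)
  keep <- len_ok & !qual_bad
  reasons <- ifelse(!len_ok, "length", "quality")[!keep]
  out <- contigs[keep, , drop = FALSE]
  attr(out, "rejects") <- factor(reasons, levels = c("length", "quality"))
  out
}
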