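# IUPAC nucleotide code -> set of compatible concrete bases (A/C/G/T).
# N in a read is compatible with nothing except an N-containing primer code.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Reverse-complement DNA strings
#'
#' Handles the full IUPAC alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Phred+33 quality string <-> integer vector
qual_to_int <- function(q) {
  lapply(q, function(s) utf8ToInt(s) - 33L)
}

int_to_qual <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

#' Read a paired FASTQ library
#'
#' Loads two FASTQ files (optionally gzipped) into the plain read-pair table
#' used throughout the pipeline.
#'
#' @param fwd_path,rev_path Paths to the forward (R1) and reverse (R2) FASTQ.
#' @return A data.frame with columns `read_id`, `fwd_seq`, `rev_seq`,
#'   `fwd_qual`, `rev_qual` (qualities as Phred+33 strings).
#' @export
read_fastq_pairs <- function(fwd_path, rev_path) {
  fwd <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fwd_path))
  rev <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(rev_path))
  if (length(fwd) != length(rev)) {
    stop("R1 and R2 have different read counts: ", fwd_path)
  }
  data.frame(
    read_id = sub("\\s.*$", "", names(fwd)),
    fwd_seq = as.character(fwd),
    rev_seq = as.character(rev),
    fwd_qual = as.character(Biostrings::quality(fwd)),
    rev_qual = as.character(Biostrings::quality(rev)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a paired FASTQ library
#'
#' @param pairs Read-pair data.frame as from [read_fastq_pairs()].
#' @param fwd_path,rev_path Output paths; `.gz` suffix triggers gzip.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, fwd_path, rev_path) {
  write_one <- function(ids, seqs, quals, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    if (length(ids)) {
      writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
    } else {
      writeLines(character(0), con)
    }
  }
  write_one(pairs$read_id, pairs$fwd_seq, pairs$fwd_qual, fwd_path)
  write_one(pairs$read_id, pairs$rev_seq, pairs$rev_qual, rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# deterministic RNG sandbox: evaluates expr under a local seed without
# disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
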