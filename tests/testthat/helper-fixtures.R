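# Shared in-code fixtures for the test suite.

# deterministic random DNA
toy_dna <- function(len, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute specific positions of a sequence
sub_at <- function(seq, pos, base = NULL) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- if (is.null(base)) setdiff(c("A", "C", "G", "T"), ch[p])[1] else base
  }
  paste(ch, collapse = "")
}

# three-reference toy taxonomy panel
toy_ref_panel <- function(len = 120, seed = 7) {
  seqs <- c(
    toy_dna(len, seed), toy_dna(len, seed + 1), toy_dna(len, seed + 2)
  )
  names(seqs) <- c(
    "refA;tax=d:Bacteria,p:Proteobacteria,c:Alphaproteobacteria,o:Rickettsiales,f:Anaplasmataceae,g:Wolbachia,s:Wolbachia_pipientis",
    "refB;tax=d:Bacteria,p:Proteobacteria,c:Gammaproteobacteria,o:Enterobacterales,f:Yersiniaceae,g:Serratia,s:Serratia_marcescens",
    "refC;tax=d:Bacteria,p:Firmicutes,c:Bacilli,o:Lactobacillales,f:Lactobacillaceae,g:Lactobacillus,s:Lactobacillus_brevis"
  )
  list(seqs = seqs, tax = parse_tax_headers(names(seqs)))
}

# build an error-free read pair for a template under a primer scheme
toy_read_pair <- function(template, scheme, read_len = 120, spacer_f = 0,
                          spacer_r = 0, qual = 37) {
  concrete <- function(p) {
    paste(vapply(strsplit(p, "")[[1]], function(b) {
      sets <- list(A = "A", C = "C", G = "G", T = "T", R = "A", Y = "C",
                   S = "G", W = "A", K = "G", M = "A", B = "C", D = "A",
                   H = "A", V = "A", N = "A")
      sets[[b]]
    }, character(1)), collapse = "")
  }
  rc <- revcomp(template)
  f <- substr(paste0(strrep("A", spacer_f), concrete(scheme$fwd_primer), template),
              1, read_len)
  r <- substr(paste0(strrep("A", spacer_r), concrete(scheme$rev_primer), rc),
              1, read_len)
  data.frame(
    read_id = "r", fwd_seq = f, rev_seq = r,
    fwd_qual = strrep(intToUtf8(qual + 33), nchar(f)),
    rev_qual = strrep(intToUtf8(qual + 33), nchar(r)),
    stringsAsFactors = FALSE
  )
}
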