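test_that("dereplication groups exact sequences and drops singletons", {
  seqs <- c(rep("AAAA", 3), "CCCC", rep("GGGG", 2))
  uq <- dereplicate(seqs)
  expect_equal(uq$seq, c("AAAA", "GGGG"))
  expect_equal(uq$count, c(3L, 2L))
  expect_warning(uq0 <- dereplicate(character(0)), "empty")
  expect_equal(nrow(uq0), 0L)
  # all singletons -> empty
  expect_equal(nrow(dereplicate(c("A", "C", "G"))), 0L)
})

test_that("UNOISE abundance-skew rule follows beta(d) = 1/2^(alpha*d+1)", {
  expect_equal(unoise_beta(1), 1 / 8)
  expect_equal(unoise_beta(2, 2), 1 / 32)
  base <- toy_dna(100, 1)
  v1 <- sub_at(base, 50)
  # count 10 vs centroid 100 at d=1: 0.1 <= 0.125 -> merged
  uq <- data.frame(seq = c(base, v1), count = c(100L, 10L))
  dz <- unoise_denoise(uq)
  expect_equal(nrow(dz$zotus), 1L)
  expect_equal(dz$zotus$count, 110)
  expect_equal(dz$members, c(1L, 1L))
  # count 20: 0.2 > 0.125 -> its own ZOTU
  uq2 <- data.frame(seq = c(base, v1), count = c(100L, 20L))
  dz2 <- unoise_denoise(uq2)
  expect_equal(nrow(dz2$zotus), 2L)
  # boundary holds analytically at d = 1..3 (centroid count 1024 keeps the
  # threshold counts integral: 128, 32, 8)
  for (d in 1:3) {
    vd <- sub_at(base, 10 + 40 * (seq_len(d) - 1))
    at <- as.integer(1024 * unoise_beta(d))
    dz_in <- unoise_denoise(data.frame(seq = c(base, vd), count = c(1024L, at)))
    dz_out <- unoise_denoise(data.frame(seq = c(base, vd),
                                        count = c(1024L, at + 1L)))
    expect_equal(nrow(dz_in$zotus), 1L, info = paste("d =", d))
    expect_equal(nrow(dz_out$zotus), 2L, info = paste("d =", d))
  }
})

test_that("denoising recovers planted templates and is idempotent", {
  set.seed(42)
  templates <- vapply(1:5, function(i) toy_dna(150, 100 + i), character(1))
  counts <- c(4000L, 2000L, 1000L, 500L, 250L)
  reads <- character(0)
  for (i in seq_along(templates)) {
    tpl <- rep(templates[i], counts[i])
    # per-base error 0.001
    err <- vapply(tpl, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(runif(length(ch)) < 0.001)
      for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    reads <- c(reads, err)
  }
  uq <- dereplicate(reads)
  dz <- unoise_denoise(uq)
  expect_setequal(dz$zotus$seq, templates)
  # count conservation: members accumulate the full dereplicated read sum
  expect_equal(sum(dz$zotus$count), sum(uq$count[!is.na(dz$members)]))
  # idempotence: denoising the centroids changes nothing
  dz2 <- unoise_denoise(dz$zotus[order(-dz$zotus$count), ])
  expect_setequal(dz2$zotus$seq, dz$zotus$seq)
  expect_equal(sort(dz2$zotus$count), sort(dz$zotus$count))
})

test_that("exact two-parent chimeras are flagged, point variants are not", {
  a <- toy_dna(200, 11)
  b <- toy_dna(200, 12)
  chim <- paste0(substr(a, 1, 100), substr(b, 101, 200))
  z <- data.frame(seq = c(a, b, chim), count = c(100L, 80L, 10L))
  expect_equal(flag_chimeras(z), c(FALSE, FALSE, TRUE))
  # under-supported parents (< 2x) do not flag
  z2 <- data.frame(seq = c(a, b, chim), count = c(15L, 80L, 10L))
  expect_equal(flag_chimeras(z2), c(FALSE, FALSE, FALSE))
  # a point variant of a single parent is not a chimera
  v <- sub_at(a, 100)
  z3 <- data.frame(seq = c(a, b, v), count = c(100L, 80L, 10L))
  expect_equal(flag_chimeras(z3), c(FALSE, FALSE, FALSE))
})

test_that("chimera recall on planted two-parent recombinants is >= 0.9", {
  set.seed(5)
  parents <- vapply(1:6, function(i) toy_dna(180, 200 + i), character(1))
  planted <- list()
  for (k in 1:10) {
    ab <- sample(6, 2)
    bp <- sample(40:140, 1)
    planted[[k]] <- paste0(substr(parents[ab[1]], 1, bp),
                           substr(parents[ab[2]], bp + 1, 180))
  }
  z <- data.frame(seq = c(parents, unlist(planted)),
                  count = c(rep(500L, 6), rep(20L, 10)))
  flags <- flag_chimeras(z)
  expect_false(any(flags[1:6]))
  expect_gte(mean(flags[7:16]), 0.9)
})

test_that("greedy 97% OTU clustering matches identity arithmetic", {
  a <- toy_dna(418, 21)
  # 12 substitutions: 406/418 = 97.1% -> same OTU
  near <- sub_at(a, seq(10, 400, length.out = 12))
  # 13 substitutions: 405/418 = 96.9% -> distinct OTUs
  far <- sub_at(a, seq(11, 401, length.out = 13))
  cl <- cluster_otus(c(a, a, near, far), c(100, 90, 50, 40))
  expect_equal(cl$otu[1], cl$otu[2])   # identical sequences share an OTU
  expect_equal(cl$otu[1], cl$otu[3])
  expect_false(cl$otu[1] == cl$otu[4])
})

test_that("greedy clustering equals the exhaustive all-pairs oracle", {
  set.seed(31)
  # 100 ZOTUs: 12 seed sequences plus mutated satellites
  seeds <- vapply(1:12, function(i) toy_dna(150, 300 + i), character(1))
  seqs <- character(0)
  for (i in 1:100) {
    s <- seeds[sample(12, 1)]
    nmut <- sample(0:6, 1)
    if (nmut > 0) s <- sub_at(s, sample(150, nmut))
    seqs <- c(seqs, s)
  }
  seqs <- unique(seqs)
  counts <- sample(1000, length(seqs))
  got <- cluster_otus(seqs, counts, identity = 0.97)
  # oracle: precompute the full identity matrix, then replay the greedy
  # rule (descending abundance, first eligible centroid in creation order)
  ord <- order(-counts, seqs)
  idm <- matrix(NA_real_, length(seqs), length(seqs))
  for (i in seq_along(seqs)) idm[, i] <- seq_identity(seqs, seqs[i])
  otu <- integer(length(seqs)); cents <- integer(0)
  for (i in ord) {
    hit <- which(vapply(cents, function(cc) idm[cc, i] >= 0.97, logical(1)))
    if (length(hit)) otu[i] <- hit[1]
    else { cents <- c(cents, i); otu[i] <- length(cents) }
  }
  expect_equal(got$otu, otu)
  # invariant: every member-centroid identity >= 0.97
  for (i in seq_along(seqs)) {
    expect_gte(idm[got$centroid[got$otu[i]], i], 0.97)
  }
})

test_that("k-mer bootstrap classifier handles exact, foreign and seeded queries", {
  panel <- toy_ref_panel()
  # query identical to one reference: full lineage at confidence 1
  cl <- classify_taxonomy(panel$seqs[[1]], panel$seqs, panel$tax, seed = 3)
  expect_true(cl$classified)
  expect_equal(unname(cl$labels[["genus"]]), "Wolbachia")
  expect_true(all(cl$confidence == 1))
  # query sharing no k-mer: unclassified
  cl0 <- classify_taxonomy(strrep("AT", 60), panel$seqs, panel$tax, seed = 3)
  expect_false(cl0$classified)
  # query shorter than k: unclassified
  expect_false(classify_taxonomy("ACGT", panel$seqs, panel$tax)$classified)
  # confidence is non-increasing from domain to genus
  q <- sub_at(panel$seqs[[2]], c(5, 30, 60, 90, 110))
  cl2 <- classify_taxonomy(q, panel$seqs, panel$tax, seed = 9)
  expect_true(all(diff(cl2$confidence) <= 1e-12))
  # fixed seed: confidences equal an independent rerun of the same stream
  cl3 <- classify_taxonomy(q, panel$seqs, panel$tax, seed = 9)
  expect_identical(cl2$confidence, cl3$confidence)
})

test_that("zotu tables conserve per-sample counts across merging", {
  per_sample <- list(
    s1 = data.frame(seq = c("AAAA", "CCCC"), count = c(10, 5)),
    s2 = data.frame(seq = c("CCCC", "GGGG"), count = c(7, 3))
  )
  tb <- build_zotu_table(per_sample)
  expect_equal(sort(colSums(tb$counts)), sort(c(s1 = 15L, s2 = 10L)))
  expect_equal(unname(tb$counts[match("CCCC", tb$seqs), "s2"]), 7L)
  # rows ordered by descending total count
  expect_true(!is.unsorted(rev(rowSums(tb$counts))))
})
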