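test_that("percentage conversion normalises columns to 100", {
  m <- matrix(c(50, 50, 0, 120), 2, 2,
              dimnames = list(c("Z1", "Z2"), c("s1", "s2")))
  p <- to_percentages(m)
  expect_equal(unname(p[, "s1"]), c(50, 50))
  expect_equal(unname(p[, "s2"]), c(0, 100))
  # arithmetic oracle on a random table
  set.seed(2)
  m2 <- matrix(rpois(30, 40), 5, 6,
               dimnames = list(paste0("Z", 1:5), paste0("s", 1:6)))
  p2 <- to_percentages(m2)
  expect_equal(colSums(p2), rep(100, 6), ignore_attr = TRUE)
  expect_equal(p2[3, 4], 100 * m2[3, 4] / sum(m2[, 4]))
  # empty sample column dropped with warning
  m3 <- cbind(m, s3 = c(0, 0))
  expect_warning(p3 <- to_percentages(m3), "empty")
  expect_equal(colnames(p3), c("s1", "s2"))
})

test_that("blank-ratio rule reproduces keep/remove decisions at the 5x boundary", {
  pct <- rbind(
    keep_10v1   = c(e1 = 10,   e2 = 0,    b1 = 1,   b2 = 0.5),
    drop_4.9v1  = c(4.9,       0,         1,        0.2),
    keep_zero_b = c(0.01,      0,         0,        0),
    keep_exact5 = c(5,         0,         1,        1),
    drop_just   = c(4.999,     0,         1,        0),
    drop_absent = c(0,         0,         2,        0)
  )
  colnames(pct) <- c("e1", "e2", "b1", "b2")
  dec <- quack_filter(pct, c("e1", "e2"), c("b1", "b2"), factor = 5)
  expect_equal(dec$keep,
               c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(dec$reason[!dec$keep], rep("ratio", 3))
  # no blanks: everything present is kept, loudly
  expect_warning(dec2 <- quack_filter(pct, c("e1", "e2"), character(0)),
                 "no blank")
  expect_equal(dec2$keep, pct[, "e1"] > 0 | pct[, "e2"] > 0,
               ignore_attr = TRUE)
  expect_error(quack_filter(pct, c("e1", "b1"), c("b1")), "overlap")
})

test_that("ratio decisions are invariant to per-sample count rescaling", {
  set.seed(4)
  counts <- matrix(rpois(60, 30), 6, 10,
                   dimnames = list(paste0("Z", 1:6), paste0("s", 1:10)))
  exp_ids <- paste0("s", 1:7); blank_ids <- paste0("s", 8:10)
  d1 <- quack_filter(to_percentages(counts), exp_ids, blank_ids)
  scaled <- sweep(counts, 2, sample(1:20, 10, replace = TRUE), "*")
  d2 <- quack_filter(to_percentages(scaled), exp_ids, blank_ids)
  expect_equal(d1$keep, d2$keep)
})

test_that("non-target taxa and chimeras are removed with per-category reasons", {
  tax <- data.frame(
    id = paste0("Z", 1:6),
    domain = c("Bacteria", "Archaea", "Eukaryota", "Bacteria", "Bacteria", "Bacteria"),
    phylum = c("Proteobacteria", "Euryarchaeota", "Ascomycota", "Cyanobacteria",
               "Proteobacteria", "Firmicutes"),
    class = NA, order = c(NA, NA, NA, "Chloroplast", "Rickettsiales", NA),
    family = c(NA, NA, NA, NA, "Mitochondria", NA),
    genus = NA, species = NA, stringsAsFactors = FALSE
  )
  counts <- matrix(1, 6, 2, dimnames = list(paste0("Z", 1:6), c("a", "b")))
  out <- remove_nontarget(counts, tax, chimera = c(rep(FALSE, 5), TRUE))
  expect_equal(rownames(out$counts), "Z1")
  expect_equal(unname(out$removed[c("Z2", "Z3", "Z4", "Z5", "Z6")]),
               c("archaea", "eukaryota", "chloroplast", "mitochondria", "chimera"))
  # set-difference oracle
  manual <- setdiff(paste0("Z", 1:6), names(out$removed))
  expect_equal(rownames(out$counts), manual)
})

test_that("ratio rule and non-target filter commute on disjoint criteria", {
  set.seed(6)
  counts <- matrix(rpois(40, 25) + 1, 8, 5,
                   dimnames = list(paste0("Z", 1:8), paste0("s", 1:5)))
  counts[1:6, 1:3] <- counts[1:6, 1:3] * 50   # true symbionts: high in samples
  counts[1:7, 4:5] <- 2                       # blanks: trace carry-over only
  counts[8, 4:5] <- 500                       # dominant reagent contaminant
  tax <- data.frame(id = paste0("Z", 1:8),
                    domain = c(rep("Bacteria", 6), "Archaea", "Eukaryota"),
                    phylum = NA, class = NA, order = NA, family = NA,
                    genus = NA, species = NA, stringsAsFactors = FALSE)
  exp_ids <- paste0("s", 1:3); blank_ids <- paste0("s", 4:5)
  pct <- to_percentages(counts)
  # order 1: ratio rule first, then the taxon filter on its survivors
  q <- quack_filter(pct, exp_ids, blank_ids)
  keep_q <- q$zotu_id[q$keep]
  nt1 <- remove_nontarget(counts[keep_q, , drop = FALSE],
                          tax[match(keep_q, tax$id), ])
  # order 2: taxon filter first, ratio rule on its survivors (percentages
  # still computed on the raw input table, as specified)
  nt2 <- remove_nontarget(counts, tax)
  q2 <- quack_filter(pct[rownames(nt2$counts), , drop = FALSE],
                     exp_ids, blank_ids)
  expect_setequal(rownames(nt1$counts), q2$zotu_id[q2$keep])
})

test_that("spike-in reads are tabulated then removed", {
  spike <- toy_dna(253, 77)
  near_spike <- sub_at(spike, 100)      # 1 mismatch, >= 99% identity
  other <- toy_dna(253, 78)
  counts <- matrix(c(100, 20, 138,
                     0,  5,  60), 3, 2,
                   dimnames = list(c("Zs", "Zs2", "Zo"), c("s1", "s2")))
  out <- split_spikein(counts, c(spike, near_spike, other),
                       c(spike_extraction = spike))
  expect_equal(unname(out$spike_reads), c(120, 5))
  expect_equal(rownames(out$counts), "Zo")
  expect_setequal(names(out$spike_zotus), c("Zs", "Zs2"))
  # zero spike-in reads flagged for downstream discard
  counts0 <- matrix(c(0, 50), 2, 1, dimnames = list(c("Zs", "Zo"), "s3"))
  out0 <- split_spikein(counts0, c(spike, other), c(spike_extraction = spike))
  expect_equal(unname(out0$spike_reads), 0)
  # an unused PCR spike-in reference is detected and dropped without use
  pcr <- toy_dna(253, 79)
  counts2 <- matrix(c(10, 30, 90), 3, 1,
                    dimnames = list(c("Zs", "Zp", "Zo"), "s1"))
  out2 <- split_spikein(counts2, c(spike, pcr, other),
                        c(spike_extraction = spike, spike_pcr = pcr))
  expect_equal(rownames(out2$counts), "Zo")
  expect_equal(unname(out2$spike_reads), 10)
  expect_equal(unname(out2$spike_zotus[["Zp"]]), "spike_pcr")
})
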