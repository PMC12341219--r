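# Synthetic communities and raw reads with known truth. The generator
# emulates the study design this pipeline targets: a site x season x sex
# sampling grid of wild flies, skewed (log-series) host species abundances
# with multiple COI genotypes per species, species/genotype/sex-structured
# endosymbiont infections with high lognormal loads, broadly distributed
# generalist bacteria, reagent contaminants shared with blank libraries,
# extraction spike-ins at known input copies, and Wolbachia COI bycatch.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

# substitute `n_subs` positions; the first and last substitution are forced
# near the sequence ends (within `edge`) so that no pair of variants can
# ever satisfy an exact two-parent bipartition by accident
mutate_anchored <- function(seq, n_subs, edge = 30L) {
  ch <- strsplit(seq, "")[[1]]
  len <- length(ch)
  pos <- c(sample(seq_len(min(edge, len)), 1),
           if (n_subs > 2) sample((edge + 1):(len - edge), n_subs - 2) else integer(0),
           sample((len - min(edge, len) + 1):len, 1))
  pos <- unique(pos)[seq_len(min(n_subs, len))]
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulation configuration presets
#'
#' `"small"` is a 24-sample cohort (2 sites x 2 seasons x 2 sexes x 3
#' individuals) of 6 host species with 2 genotypes each, 2 Wolbachia
#' strains, 1 Rickettsia strain, 5 generalist genera, 2 reagent
#' contaminants, 2 blanks and 1 positive control. `"paper-shaped"` scales
#' the grid to 6 sites and 88 individuals per site-season-sex cell with 30
#' species, mirroring the field design the pipeline targets.
#'
#' @param preset `"small"` or `"paper-shaped"`.
#' @param ... Overrides of individual fields.
#' @return A config list.
#' @export
sim_config <- function(preset = c("small", "paper-shaped"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_sites = 2L, per_cell = 3L, n_species = 6L, genotypes_per_species = 2L,
    n_wolbachia = 2L, n_rickettsia = 1L,
    generalists = c("Serratia", "Providencia", "Carnobacterium",
                    "Pseudomonas", "Lactobacillus"),
    n_contaminants = 2L, n_blanks = 2L, n_positive = 1L,
    spike_copies_levels = c(10000L, 20000L), homog_factor = 5,
    logseries_alpha = 0.8,
    wol_meanlog = log(8e5), wol_sdlog = 1,
    rick_meanlog = log(4e5), rick_sdlog = 1,
    gen_prev = 0.6, gen_meanlog = log(2e4), gen_sdlog = 1,
    cont_frac = 0.02, cont_sdlog = 0.3,
    endo_prev_female = 0.9, endo_prev_male = 0.5,
    depth_coi = 600L, depth_16s = 2000L, read_len = 250L,
    error_rate = 0, chimera_rate = 0, bycatch_frac = 0.05,
    max_sim_spacer = 3L, qual_score = 37L
  )
  if (preset == "paper-shaped") {
    cfg$n_sites <- 6L; cfg$per_cell <- 88L; cfg$n_species <- 30L
    cfg$genotypes_per_species <- 3L; cfg$n_wolbachia <- 6L
  }
  ov <- list(...)
  cfg[names(ov)] <- ov
  bad <- c(
    if (cfg$error_rate < 0 || cfg$error_rate > 1) "error_rate",
    if (cfg$chimera_rate < 0 || cfg$chimera_rate > 1) "chimera_rate",
    if (cfg$bycatch_frac < 0 || cfg$bycatch_frac > 1) "bycatch_frac",
    if (cfg$depth_coi <= 0) "depth_coi",
    if (cfg$depth_16s <= 0) "depth_16s",
    if (cfg$n_species < 1) "n_species",
    if (cfg$endo_prev_female < 0 || cfg$endo_prev_female > 1) "endo_prev_female"
  )
  if (length(bad)) stop("invalid config field(s): ", paste(bad, collapse = ", "))
  cfg
}

# lineage string helpers for the synthetic reference panel
lin16 <- function(phylum, class, order, family, genus, species) {
  sprintf("tax=d:Bacteria,p:%s,c:%s,o:%s,f:%s,g:%s,s:%s",
          phylum, class, order, family, genus, species)
}

#' Build the synthetic reference panel
#'
#' Deterministic (seeded) panel of 16S and COI reference sequences with
#' rank-annotated headers, named host barcode references, and the two
#' spike-in templates. All sequences are synthetic stand-ins generated in
#' code; lineages cover the endosymbiont and generalist genera the
#' simulated communities use, plus chloroplast, mitochondria, archaeal and
#' eukaryote entries for the non-target filters.
#'
#' @param seed Integer seed.
#' @param n_named_species Host species with named barcode references.
#' @return list: `s16` / `coi` (each `seqs` + `tax`), `barcodes` (named
#'   refs with `species`), `spikes`, `coi_ancestor`, `genus_16s`.
#' @export
ref_panel <- function(seed = 42L, n_named_species = 3L) {
  with_seed(seed, {
    g16 <- list(
      Wolbachia = lin16("Proteobacteria", "Alphaproteobacteria", "Rickettsiales",
                        "Anaplasmataceae", "Wolbachia", "Wolbachia_sp"),
      Rickettsia = lin16("Proteobacteria", "Alphaproteobacteria", "Rickettsiales",
                         "Rickettsiaceae", "Rickettsia", "Rickettsia_sp"),
      Spiroplasma = lin16("Firmicutes", "Bacilli", "Entomoplasmatales",
                          "Spiroplasmataceae", "Spiroplasma", "Spiroplasma_sp"),
      Serratia = lin16("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
                       "Yersiniaceae", "Serratia", "Serratia_sp"),
      Providencia = lin16("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
                          "Morganellaceae", "Providencia", "Providencia_sp"),
      Carnobacterium = lin16("Firmicutes", "Bacilli", "Lactobacillales",
                             "Carnobacteriaceae", "Carnobacterium", "Carnobacterium_sp"),
      Pseudomonas = lin16("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales",
                          "Pseudomonadaceae", "Pseudomonas", "Pseudomonas_sp"),
      Lactobacillus = lin16("Firmicutes", "Bacilli", "Lactobacillales",
                            "Lactobacillaceae", "Lactobacillus", "Lactobacillus_sp"),
      Cutibacterium = lin16("Actinomycetota", "Actinomycetes", "Propionibacteriales",
                            "Propionibacteriaceae", "Cutibacterium", "Cutibacterium_sp"),
      Ralstonia = lin16("Proteobacteria", "Gammaproteobacteria", "Burkholderiales",
                        "Burkholderiaceae", "Ralstonia", "Ralstonia_sp"),
      Imtechella = lin16("Bacteroidota", "Flavobacteriia", "Flavobacteriales",
                         "Flavobacteriaceae", "Imtechella", "Imtechella_halotolerans"),
      Allobacillus = lin16("Firmicutes", "Bacilli", "Bacillales",
                           "Bacillaceae", "Allobacillus", "Allobacillus_halotolerans"),
      Chloroplast = lin16("Cyanobacteria", "Cyanobacteriia", "Chloroplast",
                          "Chloroplast", "Chloroplast", "Chloroplast"),
      Mitochondria = lin16("Proteobacteria", "Alphaproteobacteria", "Rickettsiales",
                           "Mitochondria", "Mitochondria", "Mitochondria")
    )
    s16_seqs <- character(0); s16_head <- character(0)
    genus_16s <- character(0)
    for (g in names(g16)) {
      sq <- rand_dna(253L)
      s16_seqs <- c(s16_seqs, sq)
      s16_head <- c(s16_head, paste0(g, "_ref;", g16[[g]]))
      genus_16s[g] <- sq
    }
    # archaeal and eukaryote 16S/18S-like entries for domain filters
    s16_seqs <- c(s16_seqs, rand_dna(253L), rand_dna(253L))
    s16_head <- c(s16_head,
                  "Methanobrevibacter_ref;tax=d:Archaea,p:Euryarchaeota,c:Methanobacteria,o:Methanobacteriales,f:Methanobacteriaceae,g:Methanobrevibacter,s:Methanobrevibacter_sp",
                  "Saccharomyces_ref;tax=d:Eukaryota,p:Ascomycota,c:Saccharomycetes,o:Saccharomycetales,f:Saccharomycetaceae,g:Saccharomyces,s:Saccharomyces_cerevisiae")
    names(s16_seqs) <- s16_head

    # host COI: one genus ancestor, species radiate from it
    coi_ancestor <- rand_dna(418L)
    coi_wol <- mutate_anchored(rand_dna(418L), 2)
    coi_rick <- rand_dna(418L)
    coi_seqs <- c(coi_ancestor, coi_wol, coi_rick)
    names(coi_seqs) <- c(
      "Megaselia_ancestor_ref;tax=d:Eukaryota,p:Arthropoda,c:Insecta,o:Diptera,f:Phoridae,g:Megaselia,s:Megaselia_sp",
      "Wolbachia_coi_ref;tax=d:Bacteria,p:Proteobacteria,c:Alphaproteobacteria,o:Rickettsiales,f:Anaplasmataceae,g:Wolbachia,s:Wolbachia_sp",
      "Rickettsia_coi_ref;tax=d:Bacteria,p:Proteobacteria,c:Alphaproteobacteria,o:Rickettsiales,f:Rickettsiaceae,g:Rickettsia,s:Rickettsia_sp"
    )
    spikes <- c(spike_extraction = rand_dna(253L), spike_pcr = rand_dna(253L))
    list(
      s16 = list(seqs = s16_seqs, tax = parse_tax_headers(names(s16_seqs))),
      coi = list(seqs = coi_seqs, tax = parse_tax_headers(names(coi_seqs))),
      spikes = spikes, coi_ancestor = coi_ancestor,
      coi_wolbachia = coi_wol, genus_16s = genus_16s,
      n_named_species = n_named_species
    )
  })
}

#' Simulate a community truth
#'
#' Draws species barcodes (radiating from a shared ancestor, >= 5%
#' between-species divergence, <= 1% within), the sampling grid, per-sample
#' hosts from log-series species weights, endosymbiont infections
#' structured by species, genotype and sex, generalist and contaminant
#' loads, and spike-in copies per batch.
#'
#' @param config From [sim_config()].
#' @param seed Integer seed.
#' @param panel Reference panel; rebuilt from `seed` by default.
#' @return A `community_truth` list; see fields in source.
#' @export
simulate_truth <- function(config = sim_config(), seed = 1L,
                           panel = ref_panel()) {
  with_seed(seed, {
    ns <- config$n_species
    # species barcodes: ~6% from the ancestor, genotypes ~0.5% within
    species_base <- vapply(seq_len(ns), function(i) {
      mutate_anchored(panel$coi_ancestor, 25)
    }, character(1))
    n_named <- min(panel$n_named_species, ns)
    species_name <- ifelse(seq_len(ns) <= n_named,
                           sprintf("Megaselia_synthetica_%02d", seq_len(ns)),
                           NA_character_)
    genotypes <- list()
    for (i in seq_len(ns)) {
      g <- c(species_base[i],
             vapply(seq_len(config$genotypes_per_species - 1L), function(k) {
               mutate_anchored(species_base[i], 2)
             }, character(1)))
      genotypes[[i]] <- stats::setNames(g, sprintf("sp%02d_g%d", i, seq_along(g)))
    }
    # named barcode references = base sequence of the named species
    ref_barcodes <- stats::setNames(species_base[seq_len(n_named)],
                                    paste0(species_name[seq_len(n_named)], "_ref"))
    ref_barcode_species <- species_name[seq_len(n_named)]

    # bacterial strains
    strains <- list()
    add_strain <- function(id, genus, type, n_subs = 6) {
      strains[[id]] <<- list(
        strain_id = id, genus = genus, type = type,
        seq16 = mutate_anchored(panel$genus_16s[[genus]], n_subs),
        coi = if (genus == "Wolbachia" && type == "endosymbiont") {
          mutate_anchored(panel$coi_wolbachia, 6)
        } else NA_character_
      )
    }
    for (k in seq_len(config$n_wolbachia)) {
      add_strain(sprintf("wolb%d", k), "Wolbachia", "endosymbiont")
    }
    for (k in seq_len(config$n_rickettsia)) {
      add_strain(sprintf("rick%d", k), "Rickettsia", "endosymbiont")
    }
    for (g in config$generalists) add_strain(paste0("gen_", g), g, "generalist")
    for (k in seq_len(config$n_contaminants)) {
      add_strain(sprintf("cont%d", k), c("Cutibacterium", "Ralstonia")[1 + (k - 1) %% 2],
                 "contaminant")
    }
    add_strain("mock1", "Imtechella", "mock")
    add_strain("mock2", "Allobacillus", "mock")
    strain_df <- do.call(rbind, lapply(strains, function(s) {
      data.frame(s[c("strain_id", "genus", "type", "seq16", "coi")],
                 stringsAsFactors = FALSE)
    }))
    rownames(strain_df) <- strain_df$strain_id

    # endosymbiont host ranges: each strain infects 1-3 species; within a
    # species it is tied to a subset of genotypes
    endo_ids <- strain_df$strain_id[strain_df$type == "endosymbiont"]
    host_range <- lapply(seq_along(endo_ids), function(k) {
      sp <- sort(sample.int(ns, min(ns, sample(1:3, 1))))
      gts <- unlist(lapply(sp, function(i) {
        nm <- names(genotypes[[i]])
        nm[sample.int(length(nm), max(1L, length(nm) - 1L))]
      }))
      gts
    })
    names(host_range) <- endo_ids

    # sampling grid
    grid <- expand.grid(
      site = paste0("site", seq_len(config$n_sites)),
      season = c("spring", "summer"), sex = c("F", "M"),
      rep = seq_len(config$per_cell), stringsAsFactors = FALSE
    )
    n <- nrow(grid)
    sheet <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      control_type = "sample", site = grid$site, season = grid$season,
      sex = grid$sex, stringsAsFactors = FALSE
    )
    # log-series species weights
    w <- config$logseries_alpha^seq_len(ns) / seq_len(ns)
    sp_idx <- sample.int(ns, n, replace = TRUE, prob = w / sum(w))
    gt_id <- vapply(sp_idx, function(i) {
      nm <- names(genotypes[[i]])
      nm[sample.int(length(nm), 1)]
    }, character(1))
    sheet$species <- sprintf("sp%02d", sp_idx)
    sheet$genotype <- gt_id
    sheet$barcode <- vapply(seq_len(n), function(i) {
      genotypes[[sp_idx[i]]][[gt_id[i]]]
    }, character(1))
    # controls
    ctrl <- data.frame(
      sample_id = c(sprintf("BLANK%d", seq_len(config$n_blanks)),
                    sprintf("POS%d", seq_len(config$n_positive))),
      control_type = c(rep("blank", config$n_blanks),
                       rep("positive", config$n_positive)),
      site = NA, season = NA, sex = NA, species = NA, genotype = NA,
      barcode = NA, stringsAsFactors = FALSE
    )
    sheet <- rbind(sheet, ctrl)
    nall <- nrow(sheet)
    sheet$spike_copies <- config$spike_copies_levels[
      1 + (seq_len(nall) - 1) %/% ceiling(nall / length(config$spike_copies_levels))]
    sheet$homog_factor <- config$homog_factor

    # true loads (16S rRNA copies) per strain x sample; reagent
    # contaminants enter every library in proportion to its total template
    # content, so their relative abundance is comparable between blanks and
    # experimental samples (the regime the blank-ratio rule assumes)
    loads <- matrix(0, nrow(strain_df), nall,
                    dimnames = list(strain_df$strain_id, sheet$sample_id))
    for (i in seq_len(nall)) {
      ct <- sheet$control_type[i]
      if (ct == "sample") {
        for (e in endo_ids) {
          if (sheet$genotype[i] %in% host_range[[e]]) {
            prev <- if (sheet$sex[i] == "F") config$endo_prev_female else config$endo_prev_male
            if (stats::runif(1) < prev) {
              ml <- if (strain_df[e, "genus"] == "Wolbachia") config$wol_meanlog else config$rick_meanlog
              sl <- if (strain_df[e, "genus"] == "Wolbachia") config$wol_sdlog else config$rick_sdlog
              loads[e, i] <- stats::rlnorm(1, ml, sl)
            }
          }
        }
        for (s in strain_df$strain_id[strain_df$type == "generalist"]) {
          if (stats::runif(1) < config$gen_prev) {
            loads[s, i] <- stats::rlnorm(1, config$gen_meanlog, config$gen_sdlog)
          }
        }
      }
      if (ct == "positive") {
        loads[c("mock1", "mock2"), i] <- stats::rlnorm(2, log(1e5), 0.3)
      }
      # reagent contaminants reach every library, blanks included
      base <- sum(loads[, i]) +
        sheet$spike_copies[i] * config$homog_factor
      for (s in strain_df$strain_id[strain_df$type == "contaminant"]) {
        loads[s, i] <- stats::rlnorm(1, log(config$cont_frac), config$cont_sdlog) * base
      }
    }
    structure(list(
      config = config, panel = panel, sheet = sheet,
      species_base = species_base, species_name = species_name,
      genotypes = genotypes, ref_barcodes = ref_barcodes,
      ref_barcode_species = ref_barcode_species,
      strains = strain_df, host_range = host_range, loads = loads
    ), class = "community_truth")
  })
}

add_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

concretize <- function(primer) {
  paste(vapply(strsplit(primer, "")[[1]],
               function(b) sample(IUPAC_SETS[[b]], 1), character(1)),
        collapse = "")
}

# build `count` read pairs from one template for one target
template_reads <- function(template, count, target, cfg, schemes) {
  sc <- schemes[[match(target, vapply(schemes, `[[`, character(1), "target_id"))]]
  qual <- intToUtf8(rep(cfg$qual_score + 33L, cfg$read_len))
  rc <- revcomp(template)
  p1 <- concretize(sc$fwd_primer)
  p2 <- concretize(sc$rev_primer)
  sp_pool <- c("", vapply(seq_len(cfg$max_sim_spacer), rand_dna, character(1)))
  sp1 <- sample(sp_pool, count, replace = TRUE)
  sp2 <- sample(sp_pool, count, replace = TRUE)
  f <- substr(paste0(sp1, p1, template), 1, cfg$read_len)
  g <- substr(paste0(sp2, p2, rc), 1, cfg$read_len)
  if (cfg$error_rate > 0) {
    f <- vapply(f, add_errors, character(1), rate = cfg$error_rate,
                USE.NAMES = FALSE)
    g <- vapply(g, add_errors, character(1), rate = cfg$error_rate,
                USE.NAMES = FALSE)
  }
  data.frame(fwd_seq = f, rev_seq = g,
             fwd_qual = substr(qual, 1, nchar(f)),
             rev_qual = substr(qual, 1, nchar(g)),
             stringsAsFactors = FALSE)
}

#' Simulate raw mixed-target reads for every library
#'
#' Per library, reads are allocated multinomially over templates: for the
#' 16S target over bacterial strains (weight = copies / homogenate factor)
#' plus the extraction spike-in at its input copies; for COI over the host
#' barcode and, in infected hosts, the Wolbachia COI bycatch fraction.
#' Blanks carry only contaminant and spike-in templates. Primers with
#' random heterogeneity spacers are prepended and substitution errors
#' applied per base.
#'
#' @param truth From [simulate_truth()].
#' @param seed Integer seed.
#' @return list: `reads` (named list of read-pair data.frames per sample)
#'   and `truth`.
#' @export
simulate_reads <- function(truth, seed = 1L) {
  cfg <- truth$config
  schemes <- default_primer_schemes()
  with_seed(seed + 1L, {
    reads <- list()
    nall <- nrow(truth$sheet)
    alloc_16s <- matrix(0L, nrow(truth$strains) + 1L, nall,
                        dimnames = list(c(truth$strains$strain_id, "spike"),
                                        truth$sheet$sample_id))
    coi_rows <- c("host", truth$strains$strain_id)
    alloc_coi <- matrix(0L, length(coi_rows), nall,
                        dimnames = list(coi_rows, truth$sheet$sample_id))
    for (i in seq_len(nrow(truth$sheet))) {
      sid <- truth$sheet$sample_id[i]
      ct <- truth$sheet$control_type[i]
      lib <- list()
      # 16S templates
      w16 <- truth$loads[, sid] / cfg$homog_factor
      tpl16 <- truth$strains$seq16
      names(tpl16) <- truth$strains$strain_id
      w16 <- c(w16, spike = truth$sheet$spike_copies[i])
      tpl16 <- c(tpl16, spike = unname(truth$panel$spikes["spike_extraction"]))
      keep <- w16 > 0
      alloc16 <- stats::rmultinom(1, cfg$depth_16s, w16[keep])[, 1]
      alloc_16s[names(alloc16), sid] <- alloc16
      for (k in names(alloc16)[alloc16 > 0]) {
        lib[[length(lib) + 1L]] <- template_reads(tpl16[[k]], alloc16[[k]], "16S",
                                                  cfg, schemes)
      }
      # COI templates (experimental samples only)
      if (ct == "sample") {
        wol <- names(which(truth$loads[, sid] > 0))
        wol <- wol[truth$strains[wol, "genus"] == "Wolbachia" &
                     truth$strains[wol, "type"] == "endosymbiont"]
        wc <- c(host = 1 - (if (length(wol)) cfg$bycatch_frac else 0),
                stats::setNames(rep(cfg$bycatch_frac / max(1, length(wol)),
                                    length(wol)), wol))
        tplc <- c(host = truth$sheet$barcode[i],
                  stats::setNames(truth$strains[wol, "coi"], wol))
        alloc <- stats::rmultinom(1, cfg$depth_coi, wc)[, 1]
        alloc_coi[names(alloc), sid] <- alloc
        for (k in names(alloc)[alloc > 0]) {
          lib[[length(lib) + 1L]] <- template_reads(tplc[[k]], alloc[[k]], "COI",
                                                    cfg, schemes)
        }
      }
      pairs <- do.call(rbind, lib)
      pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
      pairs <- cbind(read_id = sprintf("%s_r%05d", sid, seq_len(nrow(pairs))),
                     pairs, stringsAsFactors = FALSE)
      rownames(pairs) <- NULL
      reads[[sid]] <- pairs
    }
    list(reads = reads, truth = truth,
         alloc_16s = alloc_16s, alloc_coi = alloc_coi)
  })
}

#' Write a simulated cohort to disk
#'
#' Gzipped paired FASTQ per library plus the sample sheet and reference
#' FASTA fixtures, laid out as [run_pipeline()] expects.
#'
#' @param sim From [simulate_reads()].
#' @param out_dir Output directory (created).
#' @return Invisibly, the paths list used by [run_pipeline()].
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(file.path(out_dir, "fastq"), recursive = TRUE, showWarnings = FALSE)
  for (sid in names(sim$reads)) {
    write_fastq_pairs(sim$reads[[sid]],
                      file.path(out_dir, "fastq", paste0(sid, "_R1.fastq.gz")),
                      file.path(out_dir, "fastq", paste0(sid, "_R2.fastq.gz")))
  }
  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  utils::write.table(sim$truth$sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fx <- write_fixtures(out_dir, truth = sim$truth)
  invisible(c(list(fastq_dir = file.path(out_dir, "fastq"),
                   sample_sheet = sheet_path), fx))
}

#' Write reference fixtures
#'
#' Taxonomy-annotated 16S and COI reference FASTAs, named (synthetic)
#' barcode references, and spike-in FASTA. Deterministic for a given
#' truth/panel.
#'
#' @param out_dir Output directory.
#' @param truth Optional `community_truth`; defaults to a fresh small one.
#' @return Invisibly, named list of file paths.
#' @export
write_fixtures <- function(out_dir, truth = NULL) {
  if (is.null(truth)) truth <- simulate_truth(sim_config("small"), seed = 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- truth$panel
  paths <- list(
    s16_fasta = file.path(out_dir, "ref_16s_synthetic.fasta"),
    coi_fasta = file.path(out_dir, "ref_coi_synthetic.fasta"),
    barcode_fasta = file.path(out_dir, "ref_barcodes_synthetic.fasta"),
    spike_fasta = file.path(out_dir, "spikein_synthetic.fasta")
  )
  write_fasta(p$s16$seqs, paths$s16_fasta)
  write_fasta(p$coi$seqs, paths$coi_fasta)
  write_fasta(truth$ref_barcodes, paths$barcode_fasta)
  write_fasta(p$spikes, paths$spike_fasta)
  invisible(paths)
}
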