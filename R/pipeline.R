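# End-to-end orchestration: split -> merge/QC -> denoise -> taxonomy ->
# barcode QC -> Wolbachia bycatch -> decontamination -> quantification,
# with a run manifest (config hash, seeds, file digests, per-stage counts).

#' Default pipeline parameters
#'
#' All thresholds surfaced as named keys: dominant-OTU read minimum (300),
#' arthropod read ratio (0.95), barcode length (418), OTU identity (0.97),
#' classifier confidence (0.80), blank ratio factor (5), richness threshold
#' (100 copies), Wolbachia presence (2 reads), posterior-support levels
#' (0.95 fixed effects / 0.90 associations), PSRF threshold (1.05).
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(
    max_spacer = 7L, primer_mismatches = 1L,
    min_overlap = 20L, max_mismatch_frac = 0.25,
    q_thresh = 30L, run_len = 3L,
    derep_min = 2L, alpha = 2, minsize = 2L,
    otu_identity = 0.97, sintax_cutoff = 0.80,
    min_dominant_reads = 300L, min_ratio = 0.95, barcode_len = 418L,
    species_cut = 0.03, name_identity = 0.97,
    quack_factor = 5, spike_identity = 0.99,
    homog_factor = 5, min_copies = 100,
    wol_min_reads = 2L, coi_concord_reads = 3L, s16_concord_reads = 400L,
    support_fixed = 0.95, support_assoc = 0.90, psrf_threshold = 1.05,
    seed = 1L
  )
}

#' Classify a set of sequences against a reference panel
#'
#' Vectorised wrapper over [classify_taxonomy()] returning a rank table.
#'
#' @param seqs Named character vector of query sequences.
#' @param ref_seqs,ref_tax Reference sequences and parsed taxonomy.
#' @param cutoff Confidence cutoff.
#' @param seed Base seed; query i uses `seed + i`.
#' @return data.frame with rank columns (NA below the reported depth) and
#'   `classified`.
#' @export
classify_zotus <- function(seqs, ref_seqs, ref_tax, cutoff = 0.80, seed = 1L) {
  out <- data.frame(id = names(seqs) %||% as.character(seq_along(seqs)),
                    stringsAsFactors = FALSE)
  for (r in TAX_RANKS) out[[r]] <- NA_character_
  out$classified <- FALSE
  for (i in seq_along(seqs)) {
    cl <- classify_taxonomy(seqs[[i]], ref_seqs, ref_tax, cutoff = cutoff,
                            seed = seed + i)
    if (length(cl$labels)) out[i, names(cl$labels)] <- cl$labels
    out$classified[i] <- cl$classified
  }
  out
}

validate_pipeline_config <- function(config) {
  need <- c("fastq_dir", "sample_sheet", "refs", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  for (f in c("s16_fasta", "coi_fasta", "spike_fasta")) {
    if (is.null(config$refs[[f]]) || !file.exists(config$refs[[f]])) {
      stop("missing reference file: ", f)
    }
  }
  if (!dir.exists(config$fastq_dir)) stop("fastq_dir not found: ", config$fastq_dir)
  sheet <- if (is.character(config$sample_sheet)) {
    utils::read.delim(config$sample_sheet, stringsAsFactors = FALSE)
  } else config$sample_sheet
  need_cols <- c("sample_id", "control_type", "spike_copies")
  miss <- setdiff(need_cols, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  files <- character(0)
  for (sid in sheet$sample_id) {
    for (mate in c("_R1.fastq.gz", "_R2.fastq.gz", "_R1.fastq", "_R2.fastq")) {
      f <- file.path(config$fastq_dir, paste0(sid, mate))
      if (file.exists(f)) files <- c(files, f)
    }
    found <- any(file.exists(file.path(config$fastq_dir,
                                       paste0(sid, c("_R1.fastq.gz", "_R1.fastq")))))
    if (!found) stop("no FASTQ for sample ", sid)
  }
  for (f in files) {
    con <- if (grepl("\\.gz$", f)) gzfile(f, "r") else file(f, "r")
    first <- readLines(con, n = 1)
    close(con)
    if (length(first) && !startsWith(first, "@")) {
      stop("corrupt FASTQ (no @ header): ", f)
    }
  }
  list(sheet = sheet, files = files)
}

fastq_path <- function(dir, sid, mate) {
  for (ext in c(".fastq.gz", ".fastq")) {
    f <- file.path(dir, paste0(sid, "_R", mate, ext))
    if (file.exists(f)) return(f)
  }
  stop("no FASTQ for ", sid)
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                               rownames_as),
               as.data.frame(x, stringsAsFactors = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full amplicon pipeline
#'
#' Executes every stage in order on a directory of per-sample paired FASTQ
#' files: primer-based target splitting, merging and QC, per-library
#' denoising, chimera flagging, OTU clustering, taxonomy, host barcode
#' designation and species assignment, Wolbachia COI bycatch extraction,
#' blank-based decontamination, spike-in separation and absolute
#' quantification. Writes result tables under `out_dir` and returns them
#' together with a run manifest.
#'
#' @param config list: `fastq_dir`, `sample_sheet` (path or data.frame with
#'   `sample_id`, `control_type`, `site`, `season`, `sex`, `spike_copies`,
#'   `homog_factor`), `refs` (list `s16_fasta`, `coi_fasta`,
#'   `barcode_fasta`, `spike_fasta`), `out_dir`, optional `params`
#'   overriding [default_params()].
#' @return list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  pars <- utils::modifyList(default_params(), config$params %||% list())
  pre <- validate_pipeline_config(config)
  sheet <- pre$sheet
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  schemes <- default_primer_schemes(pars$max_spacer, pars$primer_mismatches)

  s16_ref <- read_fasta(config$refs$s16_fasta)
  s16_tax <- parse_tax_headers(names(s16_ref))
  coi_ref <- read_fasta(config$refs$coi_fasta)
  coi_tax <- parse_tax_headers(names(coi_ref))
  spikes <- read_fasta(config$refs$spike_fasta)
  named_refs <- if (!is.null(config$refs$barcode_fasta) &&
                    file.exists(config$refs$barcode_fasta)) {
    read_fasta(config$refs$barcode_fasta)
  } else character(0)

  # ---- stage 1-2: split, merge, QC, dereplicate, denoise (per library)
  per_sample <- list(COI = list(), `16S` = list())
  bin_counts <- NULL
  for (sid in sheet$sample_id) {
    pairs <- read_fastq_pairs(fastq_path(config$fastq_dir, sid, 1),
                              fastq_path(config$fastq_dir, sid, 2))
    sp <- split_reads(pairs, schemes)
    row <- c(sample_id = sid, sp$counts)
    bin_counts <- rbind(bin_counts, row)
    for (tg in names(sp$targets)) {
      contigs <- merge_pairs(sp$targets[[tg]], pars$min_overlap,
                             pars$max_mismatch_frac)
      kept <- qc_filter(contigs, tg, pars$q_thresh, pars$run_len)
      uq <- suppressWarnings(dereplicate(kept$seq, pars$derep_min))
      dz <- unoise_denoise(uq, pars$alpha, pars$minsize)
      per_sample[[tg]][[sid]] <- dz$zotus
    }
  }
  bin_counts <- as.data.frame(bin_counts, stringsAsFactors = FALSE)

  # ---- stage 3: pooled tables, chimeras, OTUs, taxonomy
  res <- list()
  for (tg in c("COI", "16S")) {
    tb <- build_zotu_table(per_sample[[tg]])
    chim <- flag_chimeras(data.frame(seq = unname(tb$seqs),
                                     count = rowSums(tb$counts)))
    otus <- cluster_otus(unname(tb$seqs), rowSums(tb$counts), pars$otu_identity)
    ref <- if (tg == "COI") coi_ref else s16_ref
    rtax <- if (tg == "COI") coi_tax else s16_tax
    tax <- classify_zotus(tb$seqs, ref, rtax, pars$sintax_cutoff, pars$seed)
    res[[tg]] <- list(table = tb, chimera = chim, otu = otus$otu, tax = tax)
  }

  # ---- stage 4: host barcodes
  coi <- res$COI
  arth <- !is.na(coi$tax$phylum) & coi$tax$phylum == "Arthropoda" &
    nchar(coi$table$seqs) == pars$barcode_len & !coi$chimera
  qc_rows <- list()
  barcodes <- character(0)
  for (sid in sheet$sample_id[sheet$control_type == "sample"]) {
    counts <- coi$table$counts[arth, sid]
    bc <- select_barcode(counts, coi$otu[arth], coi$table$seqs[arth],
                         pars$min_dominant_reads, pars$min_ratio)
    qc_rows[[sid]] <- data.frame(
      sample_id = sid, pass = bc$pass,
      dominant_otu_reads = bc$dominant_otu_reads,
      arthropod_ratio = bc$arthropod_ratio,
      reject_reason = bc$reject_reason %||% NA_character_,
      stringsAsFactors = FALSE
    )
    if (bc$pass) barcodes[sid] <- bc$barcode_seq
  }
  barcode_qc <- do.call(rbind, qc_rows)
  genotype_seqs <- unique(unname(barcodes))
  names(genotype_seqs) <- paste0("G", seq_along(genotype_seqs))
  genotype_of <- names(genotype_seqs)[match(barcodes, genotype_seqs)]
  names(genotype_of) <- names(barcodes)
  ref_species <- sub("_ref$", "", names(named_refs))
  clusters <- if (length(genotype_seqs) > 1 || length(named_refs)) {
    propose_species_clusters(genotype_seqs, named_refs, ref_species,
                             pars$species_cut)
  } else {
    list(cluster = stats::setNames(rep(1L, length(genotype_seqs)),
                                   names(genotype_seqs)),
         ambiguous = FALSE)
  }
  assignments <- lapply(seq_along(genotype_seqs), function(i) {
    fb <- classify_taxonomy(genotype_seqs[[i]], coi_ref, coi_tax,
                            cutoff = pars$sintax_cutoff, seed = pars$seed + i)
    assign_name(genotype_seqs[[i]], named_refs, ref_species, fb$labels,
                pars$name_identity)
  })
  species_assign <- data.frame(
    genotype_id = names(genotype_seqs),
    cluster = clusters$cluster[names(genotype_seqs)],
    ambiguous = clusters$ambiguous[clusters$cluster[names(genotype_seqs)]],
    name = vapply(assignments, function(a) a$name %||% NA_character_, character(1)),
    level = vapply(assignments, `[[`, character(1), "level"),
    identity = vapply(assignments, `[[`, numeric(1), "identity"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  sample_cluster <- clusters$cluster[genotype_of[names(barcodes)]]
  rank_labels <- species_rank_labels(sample_cluster)

  # ---- stage 5: Wolbachia COI bycatch
  wol <- extract_wolbachia(coi$table$counts, coi$table$seqs, coi$tax,
                           coi$chimera, pars$barcode_len)
  wol_presence <- call_presence(wol$counts, pars$wol_min_reads)

  # ---- stage 6: 16S decontamination
  s16 <- res$`16S`
  exp_ids <- intersect(names(barcodes), colnames(s16$table$counts))
  blank_ids <- intersect(sheet$sample_id[sheet$control_type == "blank"],
                         colnames(s16$table$counts))
  pct <- suppressWarnings(to_percentages(s16$table$counts))
  quack <- quack_filter(pct, exp_ids, blank_ids, pars$quack_factor)
  keep_quack <- quack$keep[match(rownames(s16$table$counts), quack$zotu_id)]
  keep_quack[is.na(keep_quack)] <- FALSE
  nt <- remove_nontarget(s16$table$counts, s16$tax, s16$chimera)
  sp <- split_spikein(s16$table$counts, unname(s16$table$seqs), spikes,
                      pars$spike_identity)
  spike_rows <- rownames(s16$table$counts) %in% names(sp$spike_zotus)
  keep_final <- keep_quack &
    rownames(s16$table$counts) %in% rownames(nt$counts) & !spike_rows
  decontam_counts <- s16$table$counts[keep_final, exp_ids, drop = FALSE]
  decisions <- data.frame(
    zotu_id = rownames(s16$table$counts),
    keep = keep_final,
    reason = ifelse(keep_final, "kept",
                    ifelse(spike_rows, "spikein",
                           ifelse(rownames(s16$table$counts) %in% names(nt$removed),
                                  nt$removed[rownames(s16$table$counts)],
                                  "ratio"))),
    stringsAsFactors = FALSE, row.names = NULL
  )

  # ---- stage 7: quantification
  spike_copies <- stats::setNames(sheet$spike_copies, sheet$sample_id)
  hf <- stats::setNames(sheet$homog_factor %||% rep(pars$homog_factor, nrow(sheet)),
                        sheet$sample_id)
  ab <- abundance_table(decontam_counts, sp$spike_reads, spike_copies, hf)
  otu_of_kept <- s16$otu[keep_final]
  ab_otu <- otu_copies(ab$copies, otu_of_kept)
  rich <- data.frame(
    sample_id = colnames(ab$copies),
    total_copies = ab$total,
    sym_spike_ratio = ab$ratio,
    zotu_richness = richness_at_threshold(ab$copies, pars$min_copies),
    otu_richness = richness_at_threshold(ab_otu, pars$min_copies),
    stringsAsFactors = FALSE, row.names = NULL
  )

  # ---- stage 8: cross-marker Wolbachia concordance
  wol16_otus <- unique(otu_of_kept[
    !is.na(s16$tax$genus[keep_final]) & s16$tax$genus[keep_final] == "Wolbachia"])
  wol16_counts <- decontam_counts[otu_of_kept %in% wol16_otus, , drop = FALSE]
  concord <- NULL
  shared <- intersect(colnames(wol$counts), colnames(wol16_counts))
  shared <- intersect(shared, exp_ids)
  if (length(shared)) {
    concord <- cross_marker_agreement(
      call_presence(wol$counts[, shared, drop = FALSE], pars$coi_concord_reads),
      call_presence(wol16_counts[, shared, drop = FALSE], pars$s16_concord_reads)
    )
  }

  # ---- outputs + manifest
  out <- config$out_dir
  files <- c(
    write_tsv(bin_counts, file.path(out, "bin_counts.tsv")),
    write_tsv(res$`16S`$table$counts, file.path(out, "zotu_table_16s.tsv"), "zotu_id"),
    write_tsv(res$COI$table$counts, file.path(out, "zotu_table_coi.tsv"), "zotu_id"),
    write_tsv(barcode_qc, file.path(out, "barcode_qc.tsv")),
    write_tsv(species_assign, file.path(out, "species_assignments.tsv")),
    write_tsv(decisions, file.path(out, "decontam_decisions.tsv")),
    write_tsv(data.frame(sample_id = names(sp$spike_reads),
                         spike_reads = sp$spike_reads),
              file.path(out, "spike_counts.tsv")),
    write_tsv(ab$copies, file.path(out, "abundance_zotu.tsv"), "zotu_id"),
    write_tsv(ab_otu, file.path(out, "abundance_otu.tsv"), "otu_id"),
    write_tsv(rich, file.path(out, "sample_summary.tsv")),
    write_tsv(wol$counts, file.path(out, "wolbachia_coi_zotu.tsv"), "zotu_id"),
    write_tsv(data.frame(sample_id = names(wol_presence),
                         present = wol_presence),
              file.path(out, "wolbachia_presence.tsv"))
  )
  if (length(barcodes)) {
    files <- c(files, write_fasta(
      stats::setNames(unname(barcodes), names(barcodes)),
      file.path(out, "barcodes.fasta")))
  }
  cfg_dump <- file.path(out, "run_config.yaml")
  yaml::write_yaml(list(params = pars,
                        refs = lapply(config$refs, normalizePath)), cfg_dump)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_dump)),
    seed = pars$seed,
    inputs = as.list(tools::md5sum(pre$files)),
    outputs = as.list(tools::md5sum(files)),
    stages = list(
      split = list(n_samples = nrow(sheet)),
      denoise = list(zotus_16s = nrow(res$`16S`$table$counts),
                     zotus_coi = nrow(res$COI$table$counts)),
      barcode = list(n_pass = sum(barcode_qc$pass),
                     n_genotypes = length(genotype_seqs)),
      decontam = list(n_kept = sum(keep_final),
                      n_removed = sum(!keep_final)),
      quantify = list(n_samples = ncol(ab$copies),
                      n_discarded = length(ab$discarded)),
      wolbachia = list(n_zotus = nrow(wol$counts),
                       n_present = sum(wol_presence))
    )
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  list(
    bin_counts = bin_counts, coi = res$COI, s16 = res$`16S`,
    barcode_qc = barcode_qc, barcodes = barcodes,
    genotypes = genotype_seqs, genotype_of = genotype_of,
    species_assignments = species_assign, species_clusters = clusters,
    rank_labels = rank_labels,
    wolbachia = wol, wolbachia_presence = wol_presence,
    quack = quack, decisions = decisions, spike = sp,
    abundance = ab, abundance_otu = ab_otu, sample_summary = rich,
    concordance = concord, manifest = manifest
  )
}
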