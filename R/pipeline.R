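# End-to-end orchestration: models -> scan -> group -> classify -> promoter
# gate -> select -> motif discovery -> intergenic rescan -> regulon report.

#' Pipeline configuration
#'
#' @param scan_threshold Minimum hit score in bits (default 0).
#' @param pseudocount Profile pseudocount per base (default 1).
#' @param context_window Start-codon zone in gene coordinates
#'   (default `c(-200, 50)`).
#' @param promoter_flank Flank around Type I/II PBSs used as promoter-
#'   prediction input (default 100 bp).
#' @param promoter_threshold Combined sigma-70 score threshold in bits
#'   (`NULL` = 60% of the maximum achievable score).
#' @param meme_flank Flank around selected PBSs used as motif-discovery input
#'   (default 80 bp).
#' @param motif_widths Candidate motif widths for discovery; defaults to the
#'   palindrome-module widths.
#' @param evalue_cutoff Report cutoff for the intergenic rescan (default 10).
#' @param seed Seed for motif-discovery starts.
#' @param calibrate If `TRUE`, replace `scan_threshold` by a per-model
#'   threshold calibrated on a background surrogate via
#'   [calibrate_threshold()] with tail mass `calibrate_q`.
#' @param calibrate_q Tail mass for calibration (default 1e-5).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scan_threshold = 0,
                            pseudocount = 1,
                            context_window = c(-200, 50),
                            promoter_flank = 100L,
                            promoter_threshold = NULL,
                            meme_flank = 80L,
                            motif_widths = c(13L, 15L, 18L, 20L, 30L),
                            evalue_cutoff = 10,
                            seed = 1L,
                            calibrate = FALSE,
                            calibrate_q = 1e-5) {
  structure(
    list(scan_threshold = scan_threshold, pseudocount = pseudocount,
         context_window = context_window,
         promoter_flank = as.integer(promoter_flank),
         promoter_threshold = promoter_threshold,
         meme_flank = as.integer(meme_flank),
         motif_widths = as.integer(motif_widths),
         evalue_cutoff = evalue_cutoff, seed = as.integer(seed),
         calibrate = calibrate, calibrate_q = calibrate_q),
    class = "pipeline_config"
  )
}

extract_seq <- function(genome, contig, start, end) {
  substr(genome[[contig]], max(1L, start), min(nchar(genome[[contig]]), end))
}

#' Run the binding-site prediction pipeline
#'
#' Executes the full stage order: build the five built-in profile models with
#' the genome background, scan both strands, merge hits into PBSs, compute
#' intergenic regions and context types, predict sigma-70-like promoters in
#' the Type I/II PBS windows, select candidates (all Type I, gated Type II),
#' discover the shared motif in the flanked selected-PBS sequences by ZOOPS
#' EM, rescan the intergenic-region database with the motif PSSM, and emit
#' the regulon report. When `out_dir` is given, every stage's artifact is
#' written (TSV/BED/FASTA/MEME text) together with a run manifest recording
#' the configuration and MD5 checksums.
#'
#' @param genome Genome FASTA path, named character vector, or DNAStringSet.
#' @param annotation GFF3 path or annotation data frame (see
#'   [read_annotation()]).
#' @param config A `pipeline_config`.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @return List with every stage result: `profiles`, `background`, `hits`,
#'   `pbs`, `ig_regions`, `context`, `tally`, `density`, `promoters`,
#'   `selected`, `motif`, `mast`, `report`, `config`.
#' @export
run_pipeline <- function(genome, annotation, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[afescan] %-12s %6.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  } else {
    genome <- as_genome(genome)
  }
  if (is.character(annotation) && length(annotation) == 1L &&
      file.exists(annotation)) {
    annotation <- read_annotation(annotation)
  }
  contig_lengths <- stats::setNames(nchar(genome), names(genome))

  background <- genome_background(genome)
  profiles <- stage("models", builtin_profiles(
    pseudocount = config$pseudocount, background = background))
  thresholds <- rep(config$scan_threshold, length(profiles))
  if (isTRUE(config$calibrate)) {
    thresholds <- vapply(profiles, calibrate_threshold, 0, genome = genome,
                         q = config$calibrate_q, seed = config$seed)
  }
  hits <- stage("scan", {
    hs <- mapply(function(m, th) scan_genome(m, genome, threshold = th),
                 profiles, thresholds, SIMPLIFY = FALSE)
    do.call(rbind, hs)
  })
  rownames(hits) <- NULL
  pbs <- stage("group", group_hits(hits))
  ig <- stage("intergenic", compute_intergenic(annotation, contig_lengths))
  context <- stage("classify", classify_pbs(pbs, ig, annotation,
                                            window = config$context_window))
  tally <- tally_site_classes(pbs)
  denoms <- context_denominators(annotation, contig_lengths,
                                 window = config$context_window)
  counts <- table(factor(context$context_type, levels = c("I", "II", "III")))
  density <- density_by_type(stats::setNames(as.numeric(counts),
                                             names(counts)),
                             denoms$genome_length, denoms$tIG, denoms$t250Z)
  gate_idx <- context$context_type %in% c("I", "II")
  promoters <- stage("promoters", predict_pbs_promoters(
    pbs[gate_idx, , drop = FALSE], genome, flank = config$promoter_flank,
    threshold = config$promoter_threshold))
  selected <- stage("select", select_candidates(context, promoters))
  sel_pbs <- pbs[pbs$pbs_id %in% selected, , drop = FALSE]

  motif <- NULL
  meme_input <- character(0)
  if (nrow(sel_pbs) >= 2L) {
    meme_input <- vapply(seq_len(nrow(sel_pbs)), function(i) {
      extract_seq(genome, sel_pbs$contig[i],
                  sel_pbs$start[i] - config$meme_flank,
                  sel_pbs$end[i] + config$meme_flank)
    }, "")
    names(meme_input) <- sel_pbs$pbs_id
    motif <- stage("discover", discover_motif(
      meme_input, width = config$motif_widths, seed = config$seed,
      background = background))
  }

  ig_db <- vapply(seq_len(nrow(ig)), function(i) {
    extract_seq(genome, ig$contig[i], ig$start[i], ig$end[i])
  }, "")
  names(ig_db) <- ig$ig_id
  mast <- NULL
  if (!is.null(motif)) {
    mast <- stage("mast", mast_scan(motif, ig_db,
                                    evalue_cutoff = config$evalue_cutoff,
                                    background = background))
  }

  report <- stage("report", regulon_report(pbs, context, selected, promoters,
                                           motif, mast, ig, annotation))

  result <- list(profiles = profiles, background = background,
                 thresholds = thresholds, hits = hits, pbs = pbs,
                 ig_regions = ig, context = context, tally = tally,
                 density = density, promoters = promoters,
                 selected = selected, motif = motif, mast = mast,
                 report = report, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, genome, out_dir)
  result
}

#' Assemble the regulon report
#'
#' One row per selected PBS: coordinates, set labels, context type, the
#' nearest gene whose start codon the PBS addresses (plus the second gene for
#' a PBS shared by diverging genes), its product text, the signed distance
#' from the PBS center to the start codon (negative = upstream), membership
#' of the discovered motif, the sigma-70 overlap category of the
#' best-scoring promoter prediction in the PBS window, and the e-value of the
#' intergenic-rescan occurrence in the PBS's intergenic region (if any).
#'
#' @param pbs,context,selected,promoters,motif,mast,ig_regions,annotations
#'   Stage outputs as produced by [run_pipeline()].
#' @return Data frame, one row per selected PBS.
#' @export
regulon_report <- function(pbs, context, selected, promoters, motif, mast,
                           ig_regions, annotations) {
  sel <- pbs[pbs$pbs_id %in% selected, , drop = FALSE]
  ctx <- context[match(sel$pbs_id, context$pbs_id), , drop = FALSE]
  n <- nrow(sel)
  meme_member <- rep(FALSE, n)
  if (!is.null(motif) && nrow(motif$sites)) {
    meme_member <- sel$pbs_id %in% motif$sites$sequence_id
  }
  prom_cat <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pr <- promoters[promoters$pbs_id == sel$pbs_id[i], , drop = FALSE]
    if (!nrow(pr)) next
    best <- pr[which.max(pr$score), , drop = FALSE]
    prom_cat[i] <- overlap_category(sel$start[i], sel$end[i], best)
  }
  mast_e <- rep(NA_real_, n)
  if (!is.null(mast) && nrow(mast)) {
    for (i in seq_len(n)) {
      igid <- ctx$overlapped_ig[i]
      if (is.na(igid)) next
      m <- mast[mast$sequence_id == igid, , drop = FALSE]
      if (nrow(m)) mast_e[i] <- min(m$evalue)
    }
  }
  prod <- annotations$product[match(ctx$nearest_start_gene,
                                    annotations$gene_id)]
  out <- data.frame(
    pbs_id = sel$pbs_id,
    contig = sel$contig,
    start = sel$start,
    end = sel$end,
    set_labels = sel$set_labels,
    context_type = ctx$context_type,
    selected = TRUE,
    meme_member = meme_member,
    gene_id = ctx$nearest_start_gene,
    second_gene_id = ctx$second_gene,
    product = prod,
    distance_center_to_start = ctx$distance_center_to_start,
    promoter_overlap = prom_cat,
    mast_evalue = mast_e,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(result, genome, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_template_table(path = fp("templates.tsv"))
  for (tpl in builtin_templates()) {
    write_alignment_fasta(enumerate_variants(tpl),
                          fp(sprintf("variants_%s.fasta", tpl$id)))
  }
  write_hits(result$hits, tsv = fp("hits.tsv"), bed = fp("hits.bed"))
  write_pbs(result$pbs, tsv = fp("pbs.tsv"), bed = fp("pbs.bed"))
  ig <- result$ig_regions
  utils::write.table(ig, fp("ig_regions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(ig$contig, ig$start - 1L, ig$end, ig$ig_id,
                    as.integer(ig$is_sense), ".")
  utils::write.table(bed, fp("ig_regions.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(result$context, fp("context.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$density, fp("density.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$promoters, fp("promoters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(result$selected, fp("selected_pbs.txt"))
  if (!is.null(result$motif)) {
    write_meme_motif(result$motif, fp("motif.meme"))
    logo <- consensus_and_logo(motif_site_sequences(result$motif,
                                                    result, genome))
    utils::write.table(
      data.frame(position = seq_along(logo$ic), t(logo$counts),
                 information_bits = logo$ic),
      fp("motif_logo.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$mast)) {
    utils::write.table(result$mast, fp("mast.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(result$report, fp("report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- result$config
  manifest <- c(
    "afescan run manifest",
    paste0("package_version: ", as.character(utils::packageVersion("afescan"))),
    paste0("config: ", paste(vapply(names(cfg), function(k) {
      sprintf("%s=%s", k, paste(format(cfg[[k]]), collapse = ","))
    }, ""), collapse = "; ")),
    "checksums:"
  )
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.txt"]
  sums <- tools::md5sum(files)
  manifest <- c(manifest,
                sprintf("  %s  %s", unname(sums), basename(files)))
  writeLines(manifest, fp("manifest.txt"))
  invisible(out_dir)
}

# aligned site sequences of a discovered motif, extracted from the MEME input
motif_site_sequences <- function(motif, result, genome) {
  sel <- result$pbs[result$pbs$pbs_id %in% result$selected, , drop = FALSE]
  flank <- result$config$meme_flank
  sites <- motif$sites
  out <- character(0)
  for (i in seq_len(nrow(sites))) {
    row <- sel[sel$pbs_id == sites$sequence_id[i], , drop = FALSE]
    if (!nrow(row)) next
    lo <- max(1L, row$start - flank)
    seq_i <- extract_seq(genome, row$contig, lo,
                         min(nchar(genome[[row$contig]]), row$end + flank))
    s <- sites$offset[i]
    word <- substr(seq_i, s, s + motif$width - 1L)
    if (sites$strand[i] == "-") word <- revcomp(word)
    out <- c(out, word)
  }
  out
}
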