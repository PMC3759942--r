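# Synthetic bacterial chromosome simulator with planted operator instances
# and ground truth, so that every pipeline stage is testable without external
# downloads. Emulates a single-contig chromosome with non-overlapping CDS on
# both strands in diverging/converging/tandem arrangements.

#' Simulation configuration
#'
#' Defaults describe the standard benchmark chromosome: a 100-kb single
#' contig at 58% GC (the GC class of the At. ferrooxidans chromosome the
#' method targets), packed with 650-1400 bp genes separated by 60-160 bp
#' intergenic gaps (about 90% coding, the density of a typical bacterial
#' chromosome) in a balanced arrangement mix, and 30 consensus-sharp planted
#' instances split across the three genomic contexts.
#'
#' @param seed Integer RNG seed; the whole simulation is a deterministic
#'   function of the config including this seed.
#' @param genome_length Chromosome length in bp.
#' @param gc_content GC fraction of the background.
#' @param n_genes Number of non-overlapping CDS features, or `NULL`
#'   (default) to pack genes until the chromosome is full.
#' @param gene_length Length-2 range of gene lengths (bp).
#' @param ig_length Length-2 range of intergenic gap lengths (bp).
#' @param arrangement_mix Named fractions (`diverging`, `converging`,
#'   `tandem`) of adjacent gene-pair arrangements; must sum to 1.
#' @param plants Data frame with columns `template_id` (a built-in template
#'   id), `context` (one of `sense_IG`, `coding`, `convergent_IG`), `count`,
#'   `sharpness` (1 = sample from the template profile, 0 = background).
#' @param markov1 If `TRUE` the background is a first-order Markov chain with
#'   mild CpG-style structure instead of i.i.d. bases (robustness testing).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 100000L,
                              gc_content = 0.58,
                              n_genes = NULL,
                              gene_length = c(650L, 1400L),
                              ig_length = c(60L, 160L),
                              arrangement_mix = c(diverging = 1 / 3,
                                                  converging = 1 / 3,
                                                  tandem = 1 / 3),
                              plants = data.frame(
                                template_id = c("SP13", "MP18", "LP30",
                                                "MP20", "SP15", "MP18"),
                                context = c("sense_IG", "sense_IG", "sense_IG",
                                            "coding", "coding",
                                            "convergent_IG"),
                                count = c(5L, 5L, 5L, 5L, 5L, 5L),
                                sharpness = 1,
                                stringsAsFactors = FALSE
                              ),
                              markov1 = FALSE) {
  stopifnot(abs(sum(arrangement_mix) - 1) < 1e-9,
            gc_content > 0, gc_content < 1,
            all(plants$context %in% c("sense_IG", "coding", "convergent_IG")),
            all(plants$template_id %in% names(MODEL_LETTERS)),
            all(plants$sharpness >= 0 & plants$sharpness <= 1))
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_content = gc_content,
         n_genes = if (is.null(n_genes)) NULL else as.integer(n_genes),
         gene_length = as.integer(gene_length),
         ig_length = as.integer(ig_length),
         arrangement_mix = arrangement_mix, plants = plants,
         markov1 = markov1),
    class = "sim_config"
  )
}

# per-position sampling probabilities of a template, blended with background
template_plant_probs <- function(template, sharpness, background) {
  chars <- strsplit(template$pattern, "", fixed = TRUE)[[1]]
  probs <- vapply(chars, function(ch) {
    p <- c(A = 0, C = 0, G = 0, T = 0)
    if (ch %in% names(WILDCARD_SETS)) {
      p[WILDCARD_SETS[[ch]]] <- 1 / length(WILDCARD_SETS[[ch]])
    } else {
      p[ch] <- 1
    }
    p
  }, numeric(4L))
  sharpness * probs + (1 - sharpness) * background[DNA_BASES]
}

sample_background <- function(n, gc, markov1 = FALSE) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (!markov1) {
    return(sample(DNA_BASES, n, replace = TRUE, prob = p))
  }
  # mild first-order structure: depress CG dinucleotides, renormalise rows
  trans <- matrix(rep(p, each = 4L), 4L, 4L, dimnames = list(DNA_BASES,
                                                             DNA_BASES))
  trans["C", "G"] <- trans["C", "G"] * 0.5
  trans <- sweep(trans, 1L, rowSums(trans), "/")
  out <- character(n)
  out[1] <- sample(DNA_BASES, 1L, prob = p)
  for (i in 2:n) out[i] <- sample(DNA_BASES, 1L, prob = trans[out[i - 1L], ])
  out
}

#' Simulate a chromosome with planted operator instances
#'
#' Samples an i.i.d. background at the requested GC, lays out non-overlapping
#' CDS features left to right on both strands following the arrangement mix
#' (with an ATG planted at each 5' start and a TAA stop at each 3' end),
#' computes the intergenic structure, and splices instances sampled from the
#' named templates' emission models into regions of the requested contexts at
#' recorded positions and random strands. Deterministic given the config.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return List with `genome` (named character vector, one contig `chr`),
#'   `annotations` (gene table), `ig_regions`, `truth` (one row per planted
#'   instance: `instance_id`, `template_id`, `contig`, `start`, `end`,
#'   `strand`, `context`, `expected_type`) and `config`.
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  # ---- gene layout -------------------------------------------------------
  if (is.null(config$n_genes)) {
    # pack genes until the chromosome is full (bacterial gene density)
    glen <- integer(0); gap <- integer(0)
    pos <- 0L
    repeat {
      g <- sample(config$ig_length[1]:config$ig_length[2], 1L)
      l <- sample(config$gene_length[1]:config$gene_length[2], 1L)
      if (pos + g + l + config$ig_length[1] > L) break
      gap <- c(gap, g); glen <- c(glen, l)
      pos <- pos + g + l
    }
    gap <- c(gap, L - pos)   # terminal gap absorbs the remainder
    n_genes <- length(glen)
    if (n_genes < 2L) stop("infeasible packing: genome too short for genes")
  } else {
    n_genes <- config$n_genes
    glen <- sample(config$gene_length[1]:config$gene_length[2], n_genes,
                   replace = TRUE)
    gap <- sample(config$ig_length[1]:config$ig_length[2], n_genes + 1L,
                  replace = TRUE)
    need <- sum(glen) + sum(gap)
    if (need > L) {
      stop(sprintf(
        "infeasible packing: %d genes + gaps need %d bp but genome is %d bp",
        n_genes, need, L))
    }
  }
  starts <- integer(n_genes)
  pos <- gap[1L] + 1L
  for (i in seq_len(n_genes)) {
    starts[i] <- pos
    pos <- pos + glen[i] + gap[i + 1L]
  }
  # strands via feasible-arrangement sampling of each adjacent pair
  mix <- config$arrangement_mix
  strand <- character(n_genes)
  strand[1L] <- sample(c("+", "-"), 1L)
  for (i in 2:n_genes) {
    if (strand[i - 1L] == "+") {
      # tandem (+/+) or converging (+/-)
      pr <- c(mix[["tandem"]], mix[["converging"]])
      strand[i] <- sample(c("+", "-"), 1L, prob = pr / sum(pr))
    } else {
      # tandem (-/-) or diverging (-/+)
      pr <- c(mix[["tandem"]], mix[["diverging"]])
      strand[i] <- sample(c("-", "+"), 1L, prob = pr / sum(pr))
    }
  }
  annotations <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    contig = "chr",
    start = starts,
    end = starts + glen - 1L,
    strand = strand,
    product = sprintf("simulated protein %04d", seq_len(n_genes)),
    stringsAsFactors = FALSE
  )
  # ---- background sequence ----------------------------------------------
  bases <- sample_background(L, config$gc_content, config$markov1)
  # start/stop codons for cosmetic realism
  for (i in seq_len(nrow(annotations))) {
    s <- annotations$start[i]; e <- annotations$end[i]
    if (annotations$strand[i] == "+") {
      bases[s:(s + 2L)] <- c("A", "T", "G")
      bases[(e - 2L):e] <- c("T", "A", "A")
    } else {
      bases[(e - 2L):e] <- c("C", "A", "T")
      bases[s:(s + 2L)] <- c("T", "T", "A")
    }
  }
  ig <- compute_intergenic(annotations, c(chr = L))
  # ---- plant instances ---------------------------------------------------
  templates <- builtin_templates()
  bgfreq <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
              G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  occupied <- IRanges::IRanges()   # reserved plant intervals
  truth <- list()
  plant_margin_coding <- 280L   # keeps coding plants clear of start zones
  for (p in seq_len(nrow(config$plants))) {
    spec <- config$plants[p, ]
    tpl <- templates[[spec$template_id]]
    w <- tpl$length
    probs <- template_plant_probs(tpl, spec$sharpness, bgfreq)
    for (k in seq_len(spec$count)) {
      # candidate target windows for this context
      if (spec$context == "sense_IG") {
        regions <- ig[ig$is_sense & (ig$end - ig$start + 1L) >= w + 10L, ,
                      drop = FALSE]
        lo <- regions$start + 5L; hi <- regions$end - 5L - w + 1L
      } else if (spec$context == "convergent_IG") {
        regions <- ig[!ig$is_sense & !is.na(ig$left_gene) &
                        !is.na(ig$right_gene) &
                        (ig$end - ig$start + 1L) >= w + 10L, , drop = FALSE]
        lo <- regions$start + 5L; hi <- regions$end - 5L - w + 1L
      } else {
        a <- annotations
        deep_ok <- (a$end - a$start + 1L) >= 2L * plant_margin_coding + w
        regions <- a[deep_ok, , drop = FALSE]
        lo <- regions$start + plant_margin_coding
        hi <- regions$end - plant_margin_coding - w + 1L
      }
      ok <- which(hi >= lo)
      if (!length(ok)) {
        stop("infeasible packing: no room for a ", spec$context, " plant of ",
             spec$template_id)
      }
      placed <- FALSE
      for (attempt in 1:200) {
        r <- ok[sample.int(length(ok), 1L)]
        s <- sample(lo[r]:hi[r], 1L)
        # 40 bp clearance stops chance hit chains bridging two plants
        cand <- IRanges::IRanges(s - 40L, s + w + 39L)
        if (length(occupied) == 0L ||
            !any(IRanges::overlapsAny(cand, occupied))) {
          occupied <- c(occupied, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("infeasible packing: could not place a ", spec$context,
             " plant of ", spec$template_id, " without overlap")
      }
      inst <- vapply(seq_len(w), function(j) {
        sample(DNA_BASES, 1L, prob = probs[, j])
      }, "")
      strand_i <- sample(c("+", "-"), 1L)
      if (strand_i == "-") {
        inst <- strsplit(revcomp(paste(inst, collapse = "")), "")[[1]]
      }
      bases[s:(s + w - 1L)] <- inst
      truth[[length(truth) + 1L]] <- data.frame(
        instance_id = sprintf("plant%03d", length(truth) + 1L),
        template_id = spec$template_id, contig = "chr",
        start = s, end = s + w - 1L, strand = strand_i,
        context = spec$context, stringsAsFactors = FALSE
      )
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(instance_id = character(), template_id = character(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), context = character(),
               stringsAsFactors = FALSE)
  genome <- c(chr = paste(bases, collapse = ""))
  # expected context type of each planted interval under the context rules
  if (nrow(truth)) {
    pseudo <- data.frame(pbs_id = truth$instance_id, contig = truth$contig,
                         start = truth$start, end = truth$end,
                         center = as.integer(floor((truth$start + truth$end) / 2)),
                         stringsAsFactors = FALSE)
    calls <- classify_pbs(pseudo, ig, annotations)
    truth$expected_type <- calls$context_type[match(truth$instance_id,
                                                    calls$pbs_id)]
  } else {
    truth$expected_type <- character(0)
  }
  list(genome = genome, annotations = annotations, ig_regions = ig,
       truth = truth, config = config)
}

#' Write a simulation to FASTA + GFF3 + truth TSV
#'
#' Outputs are plain text and byte-reproducible for a given config.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"sim"`).
#' @return Named vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  dss <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(dss, fasta)
  a <- sim$annotations
  gr <- GenomicRanges::GRanges(
    seqnames = a$contig,
    ranges = IRanges::IRanges(a$start, a$end),
    strand = a$strand,
    type = "CDS", ID = a$gene_id, locus_tag = a$gene_id, product = a$product
  )
  suppressWarnings(rtracklayer::export(gr, gff, format = "gff3"))
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta, gff = gff, truth = truth))
}

#' Benchmark recovery of planted instances
#'
#' A truth instance is recovered when some PBS overlaps its interval by at
#' least `min_overlap` of the instance length. A false merge is a PBS whose
#' recovered instances include two plants that do not overlap each other.
#' Classification accuracy is computed over recovered instances: the
#' context type of the recovering PBS (largest-overlap PBS) must equal the
#' instance's `expected_type`.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param pbss PBS data frame from [group_hits()].
#' @param context_calls Data frame from [classify_pbs()] for `pbss`.
#' @param min_overlap Minimum overlap fraction of the instance (default 0.5).
#' @return List: `sensitivity`, `n_recovered`, `n_truth`, `false_merges`,
#'   `false_pbs` (PBSs overlapping no plant), `classification_accuracy`,
#'   `per_instance` (data frame).
#' @export
benchmark_recovery <- function(truth, pbss, context_calls,
                               min_overlap = 0.5) {
  n_truth <- nrow(truth)
  per <- data.frame(instance_id = truth$instance_id, recovered = FALSE,
                    pbs_id = NA_character_, called_type = NA_character_,
                    expected_type = truth$expected_type,
                    stringsAsFactors = FALSE)
  if (n_truth == 0L || nrow(pbss) == 0L) {
    return(list(sensitivity = 0, n_recovered = 0L, n_truth = n_truth,
                false_merges = 0L, false_pbs = nrow(pbss),
                classification_accuracy = NA_real_, per_instance = per))
  }
  pbs_plants <- vector("list", nrow(pbss))
  for (i in seq_len(n_truth)) {
    same <- which(pbss$contig == truth$contig[i])
    if (!length(same)) next
    ov <- pmin(pbss$end[same], truth$end[i]) -
      pmax(pbss$start[same], truth$start[i]) + 1L
    frac <- ov / (truth$end[i] - truth$start[i] + 1L)
    hit <- same[frac >= min_overlap]
    if (length(hit)) {
      best <- hit[which.max(frac[match(hit, same)])]
      per$recovered[i] <- TRUE
      per$pbs_id[i] <- pbss$pbs_id[best]
      per$called_type[i] <-
        context_calls$context_type[match(pbss$pbs_id[best],
                                         context_calls$pbs_id)]
      for (h in hit) pbs_plants[[h]] <- c(pbs_plants[[h]], i)
    }
  }
  false_merges <- 0L
  for (h in seq_along(pbs_plants)) {
    ids <- pbs_plants[[h]]
    if (length(ids) < 2L) next
    # merged plants that do not overlap one another
    combs <- utils::combn(ids, 2L)
    disjoint <- apply(combs, 2L, function(pr) {
      truth$end[pr[1]] < truth$start[pr[2]] ||
        truth$end[pr[2]] < truth$start[pr[1]]
    })
    if (any(disjoint)) false_merges <- false_merges + 1L
  }
  touched <- logical(nrow(pbss))
  for (i in seq_len(n_truth)) {
    same <- which(pbss$contig == truth$contig[i] &
                    pbss$start <= truth$end[i] & pbss$end >= truth$start[i])
    touched[same] <- TRUE
  }
  rec <- per$recovered
  acc <- if (any(rec)) {
    mean(per$called_type[rec] == per$expected_type[rec])
  } else NA_real_
  list(
    sensitivity = mean(rec),
    n_recovered = sum(rec),
    n_truth = n_truth,
    false_merges = false_merges,
    false_pbs = sum(!touched),
    classification_accuracy = acc,
    per_instance = per
  )
}
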