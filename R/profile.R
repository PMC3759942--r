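# Ungapped position-wise probabilistic profiles built from palindrome variant
# alignments, and the double-stranded genome scanner.
#
# Because the training alignments are fixed-length and ungapped, insert/delete
# states are degenerate and the model reduces to a log-odds profile scanned
# with a sliding window over both strands.

DNA_BASES <- c("A", "C", "G", "T")

# integer coding A=1 C=2 G=3 T=4, anything else (N) = 5
encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(chars, DNA_BASES)
  code[is.na(code)] <- 5L
  code
}

#' Strand-symmetrised mononucleotide background of a genome
#'
#' Computes genome-wide base frequencies and averages complementary bases
#' (A with T, C with G) so that scoring is strand-neutral. `N`s are ignored.
#'
#' @param genome Named character vector of contig sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return Named numeric vector over A,C,G,T summing to 1.
#' @export
genome_background <- function(genome) {
  genome <- as_genome(genome)
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in genome) {
    code <- encode_dna(s)
    tab <- tabulate(code[code <= 4L], nbins = 4L)
    counts <- counts + tab
  }
  if (sum(counts) == 0) stop("genome contains no unambiguous bases")
  at <- (counts[["A"]] + counts[["T"]]) / 2
  cg <- (counts[["C"]] + counts[["G"]]) / 2
  freq <- c(A = at, C = cg, G = cg, T = at)
  freq / sum(freq)
}

# coerce genome input to a named character vector of contigs
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    stop("genome must be a character vector or DNAStringSet")
  }
  if (is.null(names(out))) names(out) <- sprintf("contig%d", seq_along(out))
  out
}

#' Read a genome from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of contig sequences.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(dss) <- vapply(strsplit(names(dss), "\\s+"), `[`, "", 1L)
  as_genome(dss)
}

#' Build a position-wise profile model from a variant alignment
#'
#' Per-position emission probabilities are maximum-posterior estimates with a
#' symmetric pseudocount: `emission(i, b) = (count(i, b) + pseudocount) /
#' (n + 4 * pseudocount)`.
#'
#' @param alignment A `variant_alignment` (or character vector of equal-length
#'   sequences).
#' @param pseudocount Nonnegative pseudocount added per base (default 1).
#' @param background Background base frequencies (default uniform).
#' @param model_id,set_label Optional labels; defaulted from the alignment's
#'   template id when it is one of the built-ins.
#' @return A `profile_model`: emissions (4 x L), log-odds matrix in bits,
#'   background, pseudocount, labels.
#' @examples
#' pm <- build_profile(enumerate_variants(builtin_templates()$SP13))
#' dim(pm$emissions)  # 4 x 13
#' @export
build_profile <- function(alignment, pseudocount = 1,
                          background = c(A = .25, C = .25, G = .25, T = .25),
                          model_id = NULL, set_label = NULL) {
  if (inherits(alignment, "variant_alignment")) {
    seqs <- alignment$sequences
    tid <- alignment$template_id
  } else {
    seqs <- as.character(alignment)
    tid <- NA_character_
  }
  stopifnot(length(seqs) >= 1L, pseudocount >= 0)
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stop("ragged alignment: sequences differ in length")
  background <- background[DNA_BASES] / sum(background[DNA_BASES])
  mat <- do.call(rbind, lapply(seqs, encode_dna))
  if (any(mat > 4L)) stop("alignment sequences must be unambiguous DNA")
  n <- length(seqs)
  counts <- apply(mat, 2L, tabulate, nbins = 4L)   # 4 x L
  emissions <- (counts + pseudocount) / (n + 4 * pseudocount)
  dimnames(emissions) <- list(DNA_BASES, NULL)
  if (is.null(model_id) && !is.na(tid) && tid %in% names(MODEL_LETTERS)) {
    model_id <- unname(MODEL_LETTERS[[tid]])
    set_label <- unname(SET_LABELS[[tid]])
  }
  structure(
    list(
      model_id = if (is.null(model_id)) NA_character_ else model_id,
      set_label = if (is.null(set_label)) NA_character_ else set_label,
      template_id = tid,
      length = L,
      n_sequences = n,
      emissions = emissions,
      background = background,
      pseudocount = pseudocount,
      log_odds = log2(emissions / background)
    ),
    class = "profile_model"
  )
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model %s (set %s): %d bp, %d training sequences, pseudocount %g>\n",
              x$model_id, x$set_label, x$length, x$n_sequences, x$pseudocount))
  cat("consensus:", profile_consensus(x), "\n")
  invisible(x)
}

# per-position argmax base of a profile
profile_consensus <- function(model) {
  paste(DNA_BASES[apply(model$emissions, 2L, which.max)], collapse = "")
}

#' Build the five built-in profile models
#'
#' Convenience wrapper: enumerates variants for every built-in template and
#' builds one profile model each.
#'
#' @inheritParams build_profile
#' @return Named list of five `profile_model`s (SP13..LP30).
#' @export
builtin_profiles <- function(pseudocount = 1,
                             background = c(A = .25, C = .25, G = .25, T = .25)) {
  lapply(builtin_templates(), function(t) {
    build_profile(enumerate_variants(t), pseudocount = pseudocount,
                  background = background)
  })
}

#' Log-odds score of one window under a profile model
#'
#' `score = sum_i log2(emission(i, w_i) / background(w_i))`, in bits. For
#' `strand = "-"` the window is reverse-complemented before scoring.
#' Ambiguous bases (`N`) contribute 0 bits.
#'
#' @param model A `profile_model`.
#' @param window DNA string of length equal to the model length.
#' @param strand `"+"` or `"-"`.
#' @return Score in bits.
#' @export
score_window <- function(model, window, strand = "+") {
  stopifnot(inherits(model, "profile_model"))
  if (nchar(window) != model$length) {
    stop("window length ", nchar(window), " != model length ", model$length)
  }
  strand <- match.arg(strand, c("+", "-"))
  if (strand == "-") window <- revcomp(window)
  code <- encode_dna(window)
  lo <- rbind(model$log_odds, 0)   # 5th row: N scores as background
  s <- 0
  for (i in seq_len(model$length)) s <- s + lo[code[i], i]
  unname(s)
}

# log-odds matrix with a 5th N row (0 bits), and its reverse complement:
# rc profile column j = complement rows of column L+1-j
scan_matrices <- function(model) {
  lo <- rbind(model$log_odds, N = 0)
  L <- model$length
  lo_rc <- lo[c(4L, 3L, 2L, 1L, 5L), L:1, drop = FALSE]
  rownames(lo_rc) <- rownames(lo)
  list(fwd = lo, rev = lo_rc)
}

# vector of window scores at every start of a coded contig (one strand's
# matrix); column sweep keeps the addition order identical to score_window
sweep_scores <- function(lo, code) {
  L <- ncol(lo)
  nw <- length(code) - L + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  idx <- seq_len(nw)
  for (j in seq_len(L)) s <- s + lo[code[idx + j - 1L] + (j - 1L) * 5L]
  s
}

#' Scan a genome for non-overlapping profile hits
#'
#' Scores every window on both strands of every contig and returns a maximal
#' set of hits with `score >= threshold`, selected greedily by descending
#' score; a window overlapping an already-accepted hit of the same model is
#' discarded regardless of strand. Ties are broken by position and then by
#' strand (`+` first), so an exactly strand-symmetric locus — inevitable for
#' dyad-symmetric models with uniform wildcard columns — yields a single
#' forward-strand hit. Coordinates are 1-based inclusive on the forward
#' strand.
#'
#' @param model A `profile_model` or list of them.
#' @param genome Named character vector of contigs or DNAStringSet.
#' @param threshold Minimum score in bits (default 0).
#' @return Data frame with columns `model_id`, `set_label`, `contig`, `start`,
#'   `end`, `strand`, `score`.
#' @export
scan_genome <- function(model, genome, threshold = 0) {
  if (inherits(model, "profile_model")) model <- list(model)
  genome <- as_genome(genome)
  out <- list()
  for (m in model) {
    stopifnot(inherits(m, "profile_model"))
    mats <- scan_matrices(m)
    for (ctg in names(genome)) {
      code <- encode_dna(genome[[ctg]])
      sf <- sweep_scores(mats$fwd, code)
      sr <- sweep_scores(mats$rev, code)
      keep_f <- which(sf >= threshold)
      keep_r <- which(sr >= threshold)
      if (!length(keep_f) && !length(keep_r)) next
      cand <- data.frame(
        start = c(keep_f, keep_r),
        strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
        score = c(sf[keep_f], sr[keep_r]),
        stringsAsFactors = FALSE
      )
      sel <- greedy_select(cand, m$length, nchar(genome[[ctg]]))
      if (!nrow(sel)) next
      sel$model_id <- m$model_id
      sel$set_label <- m$set_label
      sel$contig <- ctg
      sel$end <- sel$start + m$length - 1L
      out[[length(out) + 1L]] <-
        sel[c("model_id", "set_label", "contig", "start", "end", "strand",
              "score")]
    }
  }
  if (!length(out)) {
    return(data.frame(model_id = character(), set_label = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$model_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# greedy non-overlap selection: descending score, then start, then "+" first.
# Scores are quantised to 1e-6 bits for ordering so that mathematically tied
# windows (e.g. the two strands of a perfect palindrome) break ties by
# position/strand, not by floating-point summation order.
greedy_select <- function(cand, width, contig_len) {
  ord <- order(-round(cand$score, 6), cand$start, cand$strand,
               method = "radix")
  cand <- cand[ord, , drop = FALSE]
  occupied <- logical(contig_len)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:(cand$start[i] + width - 1L)
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  sel <- cand[keep, , drop = FALSE]
  sel[order(sel$start), , drop = FALSE]
}

#' Calibrate a scan threshold on a background surrogate genome
#'
#' Fits a first-order Markov chain to the genome's dinucleotide transition
#' frequencies, simulates a surrogate sequence of the same length, scores all
#' of its windows on both strands, and returns the `(1 - q)` quantile of those
#' scores.
#'
#' @param model A `profile_model`.
#' @param genome Genome input as in [scan_genome()].
#' @param q Upper tail mass (default `1e-5`).
#' @param seed RNG seed for the surrogate simulation.
#' @return Threshold in bits.
#' @export
calibrate_threshold <- function(model, genome, q = 1e-5, seed = 1L) {
  stopifnot(inherits(model, "profile_model"), q > 0, q < 1)
  genome <- as_genome(genome)
  concat <- paste(genome, collapse = "")
  code <- encode_dna(concat)
  code <- code[code <= 4L]
  if (length(code) < 2L) stop("genome too short for calibration")
  trans <- matrix(0.25, 4L, 4L)
  tab <- table(factor(code[-length(code)], levels = 1:4),
               factor(code[-1L], levels = 1:4))
  tab <- tab + 1  # Laplace smoothing
  trans <- sweep(as.matrix(tab), 1L, rowSums(tab), "/")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(code)
  sim <- integer(n)
  sim[1L] <- sample.int(4L, 1L)
  u <- stats::runif(n - 1L)
  cum <- t(apply(trans, 1L, cumsum))
  for (i in 2L:n) {
    sim[i] <- findInterval(u[i - 1L], cum[sim[i - 1L], ], left.open = TRUE) + 1L
  }
  mats <- scan_matrices(model)
  scores <- c(sweep_scores(mats$fwd, sim), sweep_scores(mats$rev, sim))
  stats::quantile(scores, probs = 1 - q, names = FALSE, type = 1L)
}

#' Write hits to TSV and BED6
#'
#' The BED score column is the bit score times 100, rounded (it may exceed the
#' UCSC 0-1000 convention).
#'
#' @param hits Hit data frame from [scan_genome()].
#' @param tsv,bed Output paths (`NULL` to skip either).
#' @return `hits`, invisibly.
#' @export
write_hits <- function(hits, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(hits, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    bed6 <- data.frame(
      chrom = hits$contig,
      chromStart = hits$start - 1L,   # BED is 0-based half-open
      chromEnd = hits$end,
      name = paste0(hits$model_id, "_", seq_len(nrow(hits))),
      score = as.integer(round(hits$score * 100)),
      strand = hits$strand
    )
    utils::write.table(bed6, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(hits)
}
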