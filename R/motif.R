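# Motif refinement: ZOOPS expectation-maximisation motif discovery over both
# strands, an exact (discretised) PSSM score distribution for p-values, a
# MAST-like rescan of an intergenic-region database with e-values, and
# consensus/logo summaries.

IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

# window log2-probability ratios (motif vs background) at every start of a
# coded sequence, both strands; returns list(fwd, rev) of numeric vectors
window_ratios <- function(code, log_em, log_bg) {
  lo <- log_em - log_bg            # 4 x w, bits
  lo5 <- rbind(lo, N = 0)
  w <- ncol(lo)
  lo5_rc <- lo5[c(4L, 3L, 2L, 1L, 5L), w:1, drop = FALSE]
  list(fwd = sweep_scores(lo5, code), rev = sweep_scores(lo5_rc, code))
}

# one-hot-ish seed emissions from a w-mer
seed_emissions <- function(word, p0 = 0.7) {
  code <- encode_dna(word)
  w <- length(code)
  m <- matrix((1 - p0) / 3, 4L, w, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(w)) {
    if (code[j] <= 4L) m[code[j], j] <- p0 else m[, j] <- 0.25
  }
  m
}

# one ZOOPS E+M pass; returns updated model pieces and the data LLR (bits)
zoops_iterate <- function(codes, emissions, background, gamma, pseudocount,
                          oops = FALSE) {
  w <- ncol(emissions)
  log_em <- log2(emissions)
  log_bg <- log2(background[DNA_BASES])
  counts <- matrix(pseudocount, 4L, w)
  q_sum <- 0
  llr <- 0
  n_used <- 0L
  for (code in codes) {
    m1 <- length(code) - w + 1L
    if (m1 < 1L) next
    n_used <- n_used + 1L
    r <- window_ratios(code, log_em, log_bg)
    rr <- c(r$fwd, r$rev)
    m <- length(rr)
    ratio <- 2^rr
    if (oops) {
      denom <- sum(ratio) / m
      z <- ratio / (m * denom)
      llr <- llr + log2(denom)
      q_sum <- q_sum + 1
    } else {
      denom <- (1 - gamma) + gamma * sum(ratio) / m
      z <- gamma * ratio / (m * denom)
      llr <- llr + log2(denom)
      q_sum <- q_sum + sum(z)
    }
    # accumulate weighted base counts over both strands
    nz <- which(z > 1e-12)
    for (k in nz) {
      if (k <= m1) {
        win <- code[k:(k + w - 1L)]
      } else {
        win <- rev(5L - code[(k - m1):(k - m1 + w - 1L)])
        win[win == 0L] <- 5L   # N complement
      }
      ok <- win <= 4L
      idx <- win[ok] + (which(ok) - 1L) * 4L
      counts[idx] <- counts[idx] + z[k]
    }
  }
  emissions_new <- sweep(counts, 2L, colSums(counts), "/")
  gamma_new <- if (oops) 1 else min(max(q_sum / max(n_used, 1L), 1e-6), 1 - 1e-6)
  list(emissions = emissions_new, gamma = gamma_new, llr = llr)
}

# posterior site calls for a converged model
zoops_sites <- function(codes, ids, emissions, background, gamma,
                        oops = FALSE) {
  w <- ncol(emissions)
  log_em <- log2(emissions)
  log_bg <- log2(background[DNA_BASES])
  out <- list()
  for (s in seq_along(codes)) {
    code <- codes[[s]]
    m1 <- length(code) - w + 1L
    if (m1 < 1L) next
    r <- window_ratios(code, log_em, log_bg)
    rr <- c(r$fwd, r$rev)
    m <- length(rr)
    ratio <- 2^rr
    if (oops) {
      q <- 1
      z <- ratio / sum(ratio)
    } else {
      denom <- (1 - gamma) + gamma * sum(ratio) / m
      z <- gamma * ratio / (m * denom)
      q <- sum(z)
    }
    if (q <= 0.5) next
    k <- which.max(z)
    if (k <= m1) {
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = ids[s], offset = k, strand = "+", posterior = q,
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = ids[s], offset = k - m1, strand = "-", posterior = q,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sequence_id = character(), offset = integer(),
                      strand = character(), posterior = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# one-pass ZOOPS data LLR (bits) of a fixed model: no update, just the
# E-step likelihood; used to rank starting points cheaply
zoops_llr <- function(codes, emissions, background, gamma, oops = FALSE) {
  log_em <- log2(emissions)
  log_bg <- log2(background[DNA_BASES])
  w <- ncol(emissions)
  llr <- 0
  for (code in codes) {
    if (length(code) < w) next
    r <- window_ratios(code, log_em, log_bg)
    ratio <- 2^c(r$fwd, r$rev)
    m <- length(ratio)
    llr <- llr + if (oops) log2(sum(ratio) / m) else
      log2((1 - gamma) + gamma * sum(ratio) / m)
  }
  llr
}

# Rank candidate seed words by their one-pass ZOOPS LLR, batching all
# sequences into one concatenated sweep (separator runs of N are masked, so
# the quantity is exactly zoops_llr of each seed's smoothed one-hot model)
rank_seed_words <- function(codes, words, width, background, gamma,
                            oops = FALSE) {
  w <- width
  concat <- unlist(lapply(codes, function(code) c(code, rep(5L, w))))
  offs <- cumsum(c(0L, vapply(codes, length, 0L) + w))
  valid <- unlist(lapply(seq_along(codes), function(i) {
    m1 <- length(codes[[i]]) - w + 1L
    if (m1 < 1L) return(integer(0))
    offs[i] + seq_len(m1)
  }))
  seq_of <- unlist(lapply(seq_along(codes), function(i) {
    m1 <- length(codes[[i]]) - w + 1L
    rep(i, max(m1, 0L))
  }))
  m_per <- 2L * tabulate(seq_of, nbins = length(codes))
  log_bg <- log2(background[DNA_BASES])
  vapply(words, function(word) {
    log_em <- log2(seed_emissions(word))
    lo5 <- rbind(log_em - log_bg, N = 0)
    lo5_rc <- lo5[c(4L, 3L, 2L, 1L, 5L), w:1, drop = FALSE]
    sf <- sweep_scores(lo5, concat)[valid]
    sr <- sweep_scores(lo5_rc, concat)[valid]
    rs <- rowsum(2^sf + 2^sr, seq_of)
    sums <- numeric(length(codes))
    sums[as.integer(rownames(rs))] <- rs[, 1L]
    used <- m_per > 0L
    if (oops) sum(log2(sums[used] / m_per[used]))
    else sum(log2((1 - gamma) + gamma * sums[used] / m_per[used]))
  }, 0)
}

# Dirichlet-smoothing term of the MAP objective (bits); the EM with a
# pseudocount M-step is guaranteed monotone in llr + this term
map_prior_term <- function(emissions, pseudocount) {
  pseudocount * sum(log2(emissions))
}

discover_motif_width <- function(codes, ids, width, background, pseudocount,
                                 seed, n_starts, max_iter, tol, mode) {
  oops <- identical(mode, "oops")
  # deterministic, input-order-invariant starting points: pool all distinct
  # w-mers, sort them, and (if the pool is large) subsample with the given
  # seed; every candidate is ranked by its one-pass ZOOPS likelihood and the
  # best is run to convergence
  words <- unlist(lapply(codes, function(code) {
    m1 <- length(code) - width + 1L
    if (m1 < 1L) return(character(0))
    vapply(seq_len(m1), function(k) {
      paste(c("A", "C", "G", "T", "N")[code[k:(k + width - 1L)]],
            collapse = "")
    }, "")
  }))
  words <- sort(unique(words[!grepl("N", words, fixed = TRUE)]),
                method = "radix")
  if (!length(words)) stop("no ungapped windows of width ", width)
  set.seed(seed)
  pick <- if (length(words) <= n_starts) seq_along(words) else
    sort(sample.int(length(words), n_starts))
  seed_llr <- rank_seed_words(codes, words[pick], width, background, 0.5,
                              oops)
  best_word <- words[pick][which.max(seed_llr)]
  # run the best seed to convergence, tracking the MAP objective
  st <- list(emissions = seed_emissions(best_word), gamma = 0.5, llr = -Inf)
  trace <- numeric(0)
  prev_obj <- -Inf
  for (it in seq_len(max_iter)) {
    entering <- st$emissions
    st <- zoops_iterate(codes, entering, background, st$gamma, pseudocount,
                        oops)
    obj <- st$llr + map_prior_term(entering, pseudocount)
    trace <- c(trace, obj)
    if (is.finite(prev_obj) &&
        abs(obj - prev_obj) < tol * max(1, abs(prev_obj))) break
    prev_obj <- obj
  }
  sites <- zoops_sites(codes, ids, st$emissions, background, st$gamma, oops)
  structure(
    list(
      width = width,
      emissions = st$emissions,
      pssm = log2(st$emissions / background[DNA_BASES]),
      background = background[DNA_BASES],
      gamma = st$gamma,
      llr = st$llr,
      llr_trace = trace,
      sites = sites,
      mode = mode,
      consensus = paste(DNA_BASES[apply(st$emissions, 2L, which.max)],
                        collapse = "")
    ),
    class = "motif_model"
  )
}

#' ZOOPS expectation-maximisation motif discovery
#'
#' Discovers one ungapped motif shared by a set of sequences with a
#' zero-or-one-occurrence-per-sequence (ZOOPS) model over both strands: the
#' E-step computes posterior site positions, the M-step re-estimates emission
#' probabilities with a pseudocount, and iteration stops when the relative
#' change of the log-likelihood ratio (LLR, in bits, against the background
#' model) falls below `tol` or after `max_iter` iterations. Starting points
#' are drawn deterministically (given `seed`) from the sorted pool of
#' distinct subsequence windows (up to `n_starts` of them), ranked by a
#' one-pass ZOOPS likelihood, and the best is run to convergence, so the
#' result is invariant to the input sequence order. Because the M-step
#' smooths with a pseudocount, the quantity EM keeps monotone is the MAP
#' objective (data LLR plus the Dirichlet smoothing term): `llr_trace`
#' records that objective per iteration, `llr` the final data LLR. When
#' `width` has length > 1 every width is fitted and the one maximising a
#' BIC-style length-penalised LLR (`llr - 1.5 * width * log2(n)`) is
#' returned.
#'
#' @param seqs Character vector (optionally named) of >= 2 DNA sequences.
#' @param width Motif width, or vector of candidate widths (default 13:30,
#'   the palindrome-module range).
#' @param mode `"zoops"` (default) or `"oops"`.
#' @param seed Integer seed controlling the starting points.
#' @param background Background base frequencies (default uniform).
#' @param pseudocount Per-base M-step pseudocount (default 0.25).
#' @param n_starts Maximum number of starting subsequences ranked per width.
#' @param max_iter,tol Convergence controls.
#' @return A `motif_model`: `width`, `emissions` (4 x width), `pssm`
#'   (log-odds bits), `sites` (sequence_id, offset, strand, posterior),
#'   `llr` (data LLR, bits), `llr_trace` (MAP objective per iteration),
#'   `gamma`, `consensus`.
#' @export
discover_motif <- function(seqs, width = 13:30, mode = c("zoops", "oops"),
                           seed = 1L,
                           background = c(A = .25, C = .25, G = .25, T = .25),
                           pseudocount = 0.25, n_starts = 5000L,
                           max_iter = 500L, tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(length(seqs) >= 2L)
  background <- background[DNA_BASES] / sum(background[DNA_BASES])
  ids <- if (!is.null(names(seqs))) names(seqs) else
    sprintf("seq%04d", seq_along(seqs))
  codes <- lapply(toupper(seqs), encode_dna)
  width <- width[width <= max(nchar(seqs))]
  if (!length(width)) stop("all candidate widths exceed the longest sequence")
  if (length(width) == 1L) {
    return(discover_motif_width(codes, ids, width, background, pseudocount,
                                seed, n_starts, max_iter, tol, mode))
  }
  fits <- lapply(width, function(w) {
    discover_motif_width(codes, ids, w, background, pseudocount, seed,
                         n_starts, max_iter, tol, mode)
  })
  pen <- vapply(fits, function(f) {
    f$llr - 1.5 * f$width * log2(length(codes))
  }, 0)
  fits[[which.max(pen)]]
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model: width %d, %s, LLR %.2f bits, %d sites, gamma %.2f>\n",
              x$width, toupper(x$mode), x$llr, nrow(x$sites), x$gamma))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' Exact discretised score distribution of a PSSM under the background
#'
#' Integerises every PSSM entry to multiples of `granularity` and convolves
#' the per-position score distributions under the background by dynamic
#' programming, yielding the exact distribution of the integerised window
#' score. Used for position p-values in [mast_scan()].
#'
#' @param pssm 4 x w log-odds matrix (rows A,C,G,T), in bits.
#' @param background Background base frequencies.
#' @param granularity Score discretisation step in bits (default 0.01).
#' @return A `score_distribution`: integer `support`, `prob` (sums to 1
#'   within 1e-9), `granularity`.
#' @export
exact_score_distribution <- function(pssm,
                                     background = c(A = .25, C = .25,
                                                    G = .25, T = .25),
                                     granularity = 0.01) {
  stopifnot(is.matrix(pssm), nrow(pssm) == 4L, granularity > 0,
            all(is.finite(pssm)))
  background <- background[DNA_BASES] / sum(background[DNA_BASES])
  ints <- matrix(as.integer(round(pssm / granularity)), 4L, ncol(pssm))
  # DP over positions on the integerised score lattice
  cur <- c(1)
  cur_lo <- 0L
  for (j in seq_len(ncol(ints))) {
    col <- ints[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(cur) - 1L + max(col)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + col[b] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  keep <- cur > 0
  structure(
    list(
      support = (cur_lo + seq_along(cur) - 1L)[keep],
      prob = cur[keep],
      granularity = granularity
    ),
    class = "score_distribution"
  )
}

#' Upper-tail p-value of a PSSM score
#'
#' `P(score >= s)` under the background, using the discretised distribution.
#'
#' @param dist A `score_distribution`.
#' @param score Score(s) in bits.
#' @return Numeric p-value(s) in `[0, 1]`.
#' @export
score_pvalue <- function(dist, score) {
  k <- as.integer(round(score / dist$granularity))
  vapply(k, function(ki) sum(dist$prob[dist$support >= ki]), 0)
}

#' MAST-like PSSM rescan of a sequence database
#'
#' For every database sequence the best both-strand window score of the PSSM
#' is converted to a position p-value via [exact_score_distribution()], then
#' to a sequence p-value with the independence approximation
#' `1 - (1 - p)^m` over the `m` scored windows (both strands), and to an
#' e-value by multiplying by the database size. Occurrences with e-value
#' below the cutoff are returned, sorted by ascending e-value. Sequences
#' shorter than the motif width are skipped with a notice.
#'
#' @param pssm 4 x w log-odds matrix in bits (or a `motif_model`).
#' @param database Named character vector of DNA sequences (e.g. all
#'   intergenic regions).
#' @param evalue_cutoff Report cutoff (default 10).
#' @param background Background base frequencies.
#' @param granularity Discretisation step for the p-value DP.
#' @return Data frame: `sequence_id`, `offset`, `strand`, `score`,
#'   `position_pvalue`, `sequence_pvalue`, `evalue`.
#' @export
mast_scan <- function(pssm, database, evalue_cutoff = 10,
                      background = c(A = .25, C = .25, G = .25, T = .25),
                      granularity = 0.01) {
  if (inherits(pssm, "motif_model")) {
    if (missing(background)) background <- pssm$background
    pssm <- pssm$pssm
  }
  stopifnot(is.matrix(pssm), nrow(pssm) == 4L)
  background <- background[DNA_BASES] / sum(background[DNA_BASES])
  w <- ncol(pssm)
  if (is.null(names(database))) {
    names(database) <- sprintf("seq%04d", seq_along(database))
  }
  dist <- exact_score_distribution(pssm, background, granularity)
  lo5 <- rbind(pssm, N = 0)
  lo5_rc <- lo5[c(4L, 3L, 2L, 1L, 5L), w:1, drop = FALSE]
  n_db <- length(database)
  out <- list()
  for (id in names(database)) {
    seq <- database[[id]]
    if (nchar(seq) < w) {
      message("mast_scan: skipping ", id, " (shorter than motif width)")
      next
    }
    code <- encode_dna(seq)
    sf <- sweep_scores(lo5, code)
    sr <- sweep_scores(lo5_rc, code)
    m <- length(sf) + length(sr)
    all_s <- c(sf, sr)
    k <- which.max(all_s)
    best <- all_s[k]
    if (k <= length(sf)) {
      offset <- k; strand <- "+"
    } else {
      offset <- k - length(sf); strand <- "-"
    }
    p_pos <- score_pvalue(dist, best)
    p_seq <- 1 - (1 - p_pos)^m
    out[[length(out) + 1L]] <- data.frame(
      sequence_id = id, offset = offset, strand = strand, score = best,
      position_pvalue = p_pos, sequence_pvalue = p_seq,
      evalue = p_seq * n_db, stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sequence_id = character(), offset = integer(),
               strand = character(), score = numeric(),
               position_pvalue = numeric(), sequence_pvalue = numeric(),
               evalue = numeric(), stringsAsFactors = FALSE)
  res <- res[res$evalue < evalue_cutoff, , drop = FALSE]
  res <- res[order(res$evalue, res$sequence_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Consensus sequence and per-column information content of aligned sites
#'
#' The consensus is the per-column plurality base, with ties encoded as the
#' IUPAC ambiguity code of the tied set. Information content per column is
#' `2 + sum_b f_b log2 f_b` bits under a uniform background (0 log 0 = 0).
#'
#' @param sites Character vector of equal-length aligned sequences.
#' @return List: `consensus` (string), `ic` (numeric per column, bits),
#'   `counts` (4 x width matrix).
#' @export
consensus_and_logo <- function(sites) {
  stopifnot(length(sites) >= 1L)
  L <- nchar(sites[1])
  if (any(nchar(sites) != L)) stop("sites must be equal-length")
  mat <- do.call(rbind, lapply(sites, encode_dna))
  counts <- apply(mat, 2L, function(col) tabulate(col[col <= 4L], nbins = 4L))
  dimnames(counts) <- list(DNA_BASES, NULL)
  cons <- vapply(seq_len(L), function(j) {
    cj <- counts[, j]
    top <- DNA_BASES[cj == max(cj) & cj > 0]
    if (!length(top)) return("N")
    unname(IUPAC_FROM_SET[paste(sort(top), collapse = "")])
  }, "")
  ic <- vapply(seq_len(L), function(j) {
    f <- counts[, j] / max(sum(counts[, j]), 1L)
    f <- f[f > 0]
    2 + sum(f * log2(f))
  }, 0)
  list(consensus = paste(cons, collapse = ""), ic = ic, counts = counts)
}

#' Write a motif in MEME minimal text format
#'
#' @param motif A `motif_model`.
#' @param path Output path.
#' @param name Motif name in the file.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(motif, path, name = "motif1") {
  stopifnot(inherits(motif, "motif_model"))
  con <- file(path, "w")
  on.exit(close(con))
  bg <- motif$background
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            motif$width, max(nrow(motif$sites), 1L))
  ), con)
  apply(motif$emissions, 2L, function(col) {
    writeLines(sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4]),
               con)
  })
  invisible(path)
}
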