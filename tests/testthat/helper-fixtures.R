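# shared fixtures: random sequences, tiny annotations, planted instances

random_dna <- function(n, seed = NULL,
                       prob = c(A = .25, C = .25, G = .25, T = .25)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# consensus instance of a template: fixed positions exact, wildcards sampled
template_instance <- function(template, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(template$pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    sets <- afescan:::WILDCARD_SETS
    if (ch %in% names(sets)) sample(sets[[ch]], 1L) else ch
  }, ""), collapse = "")
}

splice_at <- function(seq, sub, at) {
  substr(seq, at, at + nchar(sub) - 1L) <- sub
  seq
}

# a minimal three-gene annotation on a 3 kb contig:
#   gene1 (-) [201,700]   gene2 (+) [901,1500]   gene3 (+) [1701,2300]
# IGs: [1,200] (right flank -, terminal) sense via gene1(-)? gene1 is "-" so
# its start abuts its RIGHT ig; [701,900] diverging (gene1- start, gene2+
# start) -> sense; [1501,1700] tandem (+/+) -> sense via gene3; [2301,3000]
# terminal, left flank gene3 "+" -> not sense
tiny_annotation <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3"),
    contig = "chr",
    start = c(201L, 901L, 1701L),
    end = c(700L, 1500L, 2300L),
    strand = c("-", "+", "+"),
    product = c("alpha", "beta", "gamma"),
    stringsAsFactors = FALSE
  )
}

tiny_contig_lengths <- c(chr = 3000L)

# random non-overlapping annotation layout on one contig
random_annotation <- function(n_genes, contig_len, seed) {
  set.seed(seed)
  glen <- sample(100:300, n_genes, replace = TRUE)
  gap <- sample(20:120, n_genes + 1L, replace = TRUE)
  while (sum(glen) + sum(gap) > contig_len) {
    n_genes <- n_genes - 1L
    glen <- glen[seq_len(n_genes)]
    gap <- gap[seq_len(n_genes + 1L)]
  }
  starts <- cumsum(c(gap[1L] + 1L,
                     utils::head(glen, -1L) + gap[2:n_genes]))
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    contig = "chr",
    start = as.integer(starts),
    end = as.integer(starts + glen - 1L),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    product = NA_character_,
    stringsAsFactors = FALSE
  )
}

# brute-force scanner: enumerates every window on both strands and scores
# each by summing per-position log-odds terms for that window (independent
# of the scanner's column-sweep), then applies the same greedy rule
brute_force_scan <- function(model, genome, threshold = 0) {
  genome <- afescan:::as_genome(genome)
  lo <- rbind(model$log_odds, N = 0)
  L <- model$length
  out <- list()
  for (ctg in names(genome)) {
    code <- afescan:::encode_dna(genome[[ctg]])
    nw <- length(code) - L + 1L
    if (nw < 1L) next
    starts <- integer(0); strands <- character(0); scores <- numeric(0)
    pos <- seq_len(L)
    for (i in seq_len(nw)) {
      win <- code[i:(i + L - 1L)]
      # reverse complement of the window, scored left to right
      rcw <- rev(5L - win)
      rcw[rcw == 0L] <- 5L
      for (st in c("+", "-")) {
        w <- if (st == "+") win else rcw
        sc <- sum(lo[cbind(w, pos)])
        if (sc >= threshold) {
          starts <- c(starts, i); strands <- c(strands, st)
          scores <- c(scores, sc)
        }
      }
    }
    if (!length(starts)) next
    cand <- data.frame(start = starts, strand = strands, score = scores,
                       stringsAsFactors = FALSE)
    sel <- afescan:::greedy_select(cand, L, length(code))
    if (!nrow(sel)) next
    sel$contig <- ctg
    sel$end <- sel$start + L - 1L
    out[[length(out) + 1L]] <- sel
  }
  if (!length(out)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), c("contig", "start", "end", "strand",
                                      "score")]
}

# random log-odds PSSM of a given width
random_pssm <- function(width, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(4L * width, sd = 1.5), 4L, width,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}

# sequences with one planted consensus instance each; returns list with
# seqs, offsets, instances
planted_set <- function(template, n_seqs, len, seed,
                        gc = 0.5) {
  set.seed(seed)
  w <- template$length
  stopifnot(len > w)
  seqs <- character(n_seqs)
  offsets <- integer(n_seqs)
  insts <- character(n_seqs)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (i in seq_len(n_seqs)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = p), collapse = "")
    inst <- template_instance(template)
    off <- sample.int(len - w + 1L, 1L)
    seqs[i] <- splice_at(s, inst, off)
    offsets[i] <- off
    insts[i] <- inst
  }
  names(seqs) <- sprintf("s%03d", seq_len(n_seqs))
  list(seqs = seqs, offsets = offsets, instances = insts)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
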