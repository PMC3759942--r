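# Sigma-70 promoter element prediction: a consensus-PWM locator for paired
# -35/-10 hexamers with a 15-19 bp spacer. This is the package's own
# sigma70-like predictor; its output is labelled as such in reports.

# Literature-consensus positional weights for the E. coli sigma-70 hexamers
# (consensus-base frequencies after Harley & Reynolds-style compilations;
# the remaining mass is split evenly over the other three bases).
sigma70_pwms <- function(background = c(A = .25, C = .25, G = .25, T = .25)) {
  build <- function(consensus, cons_freq) {
    bases <- strsplit(consensus, "")[[1]]
    m <- matrix(NA_real_, 4L, length(bases), dimnames = list(DNA_BASES, NULL))
    for (j in seq_along(bases)) {
      m[, j] <- (1 - cons_freq[j]) / 3
      m[bases[j], j] <- cons_freq[j]
    }
    log2(m / background[DNA_BASES])
  }
  list(
    minus35 = build("TTGACA", c(.78, .82, .68, .58, .52, .54)),
    minus10 = build("TATAAT", c(.82, .89, .52, .59, .49, .89))
  )
}

# best-possible combined score of the two hexamer PWMs
sigma70_max_score <- function(pwms = sigma70_pwms()) {
  sum(apply(pwms$minus35, 2L, max)) + sum(apply(pwms$minus10, 2L, max))
}

# score all placements on one coded strand; returns data.frame of placements
# (coordinates on that strand)
sigma70_scan_strand <- function(code, pwms, spacers) {
  L <- length(code)
  out <- list()
  s35 <- sweep_scores(rbind(pwms$minus35, N = -Inf), code)
  s10 <- sweep_scores(rbind(pwms$minus10, N = -Inf), code)
  for (sp in spacers) {
    # -35 at i, -10 at i + 6 + sp
    n <- L - (12L + sp) + 1L
    if (n < 1L) next
    i <- seq_len(n)
    comb <- s35[i] + s10[i + 6L + sp]
    out[[length(out) + 1L]] <- data.frame(
      m35_start = i, spacer = sp, score = comb
    )
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Predict sigma-70-like promoter element pairs
#'
#' Scores every placement of a -35 (TTGACA-anchored) and -10
#' (TATAAT-anchored) hexamer pair with a spacer of 15-19 bp on both strands
#' of `seq`, using mismatch-tolerant log-odds PWMs, and returns the
#' placements with combined score at or above the threshold, best first,
#' greedily non-overlapping (overlap judged on the full -35..-10 span).
#'
#' @param seq A DNA string (length >= 27).
#' @param threshold Minimum combined score in bits; default 60% of the
#'   maximum achievable combined score.
#' @param background Background base frequencies for the log-odds.
#' @return Data frame: `strand`, `m35_start`, `m35_end`, `spacer`,
#'   `m10_start`, `m10_end`, `score`. Coordinates are 1-based on the input
#'   sequence; on the `-` strand the -10 element lies left of the -35 in
#'   input coordinates.
#' @export
predict_sigma70 <- function(seq, threshold = NULL,
                            background = c(A = .25, C = .25, G = .25, T = .25)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  pwms <- sigma70_pwms(background)
  if (is.null(threshold)) threshold <- 0.6 * sigma70_max_score(pwms)
  L <- nchar(seq)
  empty <- data.frame(strand = character(), m35_start = integer(),
                      m35_end = integer(), spacer = integer(),
                      m10_start = integer(), m10_end = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (L < 27L) return(empty)
  spacers <- 15:19
  cand <- list()
  fw <- sigma70_scan_strand(encode_dna(seq), pwms, spacers)
  if (!is.null(fw)) {
    fw$strand <- "+"
    fw$m35_end <- fw$m35_start + 5L
    fw$m10_start <- fw$m35_start + 6L + fw$spacer
    fw$m10_end <- fw$m10_start + 5L
    cand[[1L]] <- fw
  }
  rv <- sigma70_scan_strand(encode_dna(revcomp(seq)), pwms, spacers)
  if (!is.null(rv)) {
    rv$strand <- "-"
    # map hexamers at [i, i+5] and [i+6+sp, i+11+sp] on the reverse strand
    # back to input coordinates (rc position p -> L - p + 1)
    i <- rv$m35_start
    rv$m35_start <- L - i - 4L
    rv$m35_end <- L - i + 1L
    rv$m10_start <- L - i - 10L - rv$spacer
    rv$m10_end <- L - i - 5L - rv$spacer
    cand[[length(cand) + 1L]] <- rv
  }
  cand <- do.call(rbind, cand)
  cand <- cand[is.finite(cand$score) & cand$score >= threshold, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  span_lo <- pmin(cand$m35_start, cand$m10_start)
  span_hi <- pmax(cand$m35_end, cand$m10_end)
  ord <- order(-cand$score, span_lo, cand$strand, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  span_lo <- span_lo[ord]; span_hi <- span_hi[ord]
  occupied <- logical(L)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- span_lo[i]:span_hi[i]
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  res <- cand[keep, c("strand", "m35_start", "m35_end", "spacer",
                      "m10_start", "m10_end", "score")]
  res <- res[order(-res$score, res$m35_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Categorise the positional relation of a PBS to a promoter prediction
#'
#' `"overlaps -35"` if the PBS interval shares >= 1 bp with the -35 hexamer
#' (precedence over the -10), else `"overlaps -10"`, else `"near"` if the PBS
#' is within 10 bp of either hexamer, else `"none"`.
#'
#' @param pbs_start,pbs_end PBS interval (same coordinate system as the
#'   prediction).
#' @param prediction One row of a [predict_sigma70()] result.
#' @return One of `"overlaps -35"`, `"overlaps -10"`, `"near"`, `"none"`.
#' @export
overlap_category <- function(pbs_start, pbs_end, prediction) {
  ov <- function(s, e) pbs_start <= e && pbs_end >= s
  near <- function(s, e) (pbs_start <= e + 10L) && (pbs_end >= s - 10L)
  if (ov(prediction$m35_start, prediction$m35_end)) return("overlaps -35")
  if (ov(prediction$m10_start, prediction$m10_end)) return("overlaps -10")
  if (near(prediction$m35_start, prediction$m35_end) ||
      near(prediction$m10_start, prediction$m10_end)) return("near")
  "none"
}

#' Predict promoters in the flanked windows of PBSs
#'
#' Extracts each PBS's window (PBS plus `flank` bp each side, clipped to the
#' contig), runs [predict_sigma70()] on it, and returns all predictions in
#' genomic coordinates, tagged with the owning `pbs_id`.
#'
#' @param pbss PBS data frame.
#' @param genome Genome as in [scan_genome()].
#' @param flank Flank size in bp (default 100).
#' @param threshold Passed to [predict_sigma70()].
#' @return Data frame of predictions with `pbs_id` and genomic coordinates.
#' @export
predict_pbs_promoters <- function(pbss, genome, flank = 100L,
                                  threshold = NULL) {
  genome <- as_genome(genome)
  out <- list()
  for (i in seq_len(nrow(pbss))) {
    ctg <- pbss$contig[i]
    lo <- max(1L, pbss$start[i] - flank)
    hi <- min(nchar(genome[[ctg]]), pbss$end[i] + flank)
    window <- substr(genome[[ctg]], lo, hi)
    pr <- predict_sigma70(window, threshold = threshold)
    if (!nrow(pr)) next
    for (col in c("m35_start", "m35_end", "m10_start", "m10_end")) {
      pr[[col]] <- pr[[col]] + lo - 1L
    }
    pr$pbs_id <- pbss$pbs_id[i]
    pr$contig <- ctg
    out[[length(out) + 1L]] <- pr
  }
  if (!length(out)) {
    return(data.frame(strand = character(), m35_start = integer(),
                      m35_end = integer(), spacer = integer(),
                      m10_start = integer(), m10_end = integer(),
                      score = numeric(), pbs_id = character(),
                      contig = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
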