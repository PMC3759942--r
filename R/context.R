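# Genomic context of predicted binding sites: intergenic regions with
# "senseness", Type I/II/III classification, density statistics, and the
# candidate-selection rule.
#
# Coordinates are 1-based inclusive; a gene's start codon sits at the 5'
# boundary of its CDS interval on its own strand (start for "+", end for "-").

#' Read a gene annotation from GFF3
#'
#' Imports CDS features (optionally other genic feature types) via
#' \pkg{rtracklayer} and returns the flat annotation table used by the
#' context module. The gene id is taken from the `ID` or `locus_tag`
#' attribute, the product text from `product` or `Note`.
#'
#' @param path GFF3 file path.
#' @param feature_types Feature types treated as genic (default `"CDS"`).
#' @return Data frame with `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `product`.
#' @export
read_annotation <- function(path, feature_types = "CDS") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  md <- S4Vectors::mcols(gr)
  pick <- function(field, alt, default) {
    v <- if (field %in% names(md)) as.character(md[[field]]) else
      rep(NA_character_, length(gr))
    a <- if (alt %in% names(md)) as.character(md[[alt]]) else
      rep(NA_character_, length(gr))
    out <- ifelse(is.na(v) | v == "", a, v)
    ifelse(is.na(out) | out == "", default, out)
  }
  data.frame(
    gene_id = pick("ID", "locus_tag", sprintf("gene%04d", seq_along(gr))),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = pick("product", "Note", NA_character_),
    stringsAsFactors = FALSE
  )
}

validate_annotation <- function(annotations, contig_lengths) {
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in%
                  names(annotations)))
  if (!all(annotations$strand %in% c("+", "-"))) {
    stop("gene strands must be '+' or '-'")
  }
  for (ctg in unique(annotations$contig)) {
    a <- annotations[annotations$contig == ctg, , drop = FALSE]
    len <- contig_lengths[[ctg]]
    if (is.null(len) || is.na(len)) stop("unknown contig length for ", ctg)
    if (any(a$start < 1L) || any(a$end > len)) {
      stop("annotation outside contig bounds on ", ctg)
    }
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1L && any(a$start[-1L] <= a$end[-nrow(a)])) {
      bad <- which(a$start[-1L] <= a$end[-nrow(a)])[1L]
      stop(sprintf("overlapping CDS on %s: %s and %s", ctg,
                   a$gene_id[bad], a$gene_id[bad + 1L]))
    }
  }
  invisible(annotations)
}

#' Compute intergenic regions with senseness
#'
#' Intergenic (IG) regions are the complement of the union of CDS intervals on
#' each contig. An IG region is "sense" if at least one flanking gene reads
#' away from the region into its own body, i.e. that gene's start codon abuts
#' the region (a forward-strand right flank, or a reverse-strand left flank).
#' The gap between the stop codons of converging genes is therefore not a
#' sense IG region. Terminal unannotated stretches have one `NA` flank and
#' follow the single-flank rule.
#'
#' @param annotations Annotation data frame (see [read_annotation()]).
#' @param contig_lengths Named vector of contig lengths.
#' @return Data frame: `ig_id`, `contig`, `start`, `end`, `left_gene`,
#'   `right_gene`, `is_sense`.
#' @export
compute_intergenic <- function(annotations, contig_lengths) {
  validate_annotation(annotations, contig_lengths)
  out <- list()
  for (ctg in names(contig_lengths)) {
    len <- contig_lengths[[ctg]]
    a <- annotations[annotations$contig == ctg, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = 1L, end = len,
        left_gene = NA_character_, right_gene = NA_character_,
        is_sense = FALSE, stringsAsFactors = FALSE
      )
      next
    }
    ir <- IRanges::IRanges(a$start, a$end)
    gaps <- IRanges::gaps(ir, start = 1L, end = len)
    if (!length(gaps)) next
    gs <- IRanges::start(gaps)
    ge <- IRanges::end(gaps)
    # flanking genes: gene ending at gs-1 / starting at ge+1
    left_idx <- match(gs - 1L, a$end)
    right_idx <- match(ge + 1L, a$start)
    left_strand <- a$strand[left_idx]
    right_strand <- a$strand[right_idx]
    sense_left <- !is.na(left_idx) & left_strand == "-"
    sense_right <- !is.na(right_idx) & right_strand == "+"
    out[[length(out) + 1L]] <- data.frame(
      contig = ctg, start = gs, end = ge,
      left_gene = a$gene_id[left_idx],
      right_gene = a$gene_id[right_idx],
      is_sense = sense_left | sense_right,
      stringsAsFactors = FALSE
    )
  }
  ig <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), start = integer(), end = integer(),
               left_gene = character(), right_gene = character(),
               is_sense = logical(), stringsAsFactors = FALSE)
  if (nrow(ig)) ig <- ig[order(ig$contig, ig$start), , drop = FALSE]
  rownames(ig) <- NULL
  if (nrow(ig)) ig <- cbind(ig_id = sprintf("IG_%04d", seq_len(nrow(ig))), ig,
                            stringsAsFactors = FALSE)
  else ig <- cbind(ig_id = character(), ig)
  ig
}

# strand-aware start codon position of each gene (genomic coordinate)
gene_start_pos <- function(annotations) {
  ifelse(annotations$strand == "+", annotations$start, annotations$end)
}

# signed center-to-start distance in gene coordinates: negative = upstream
signed_distance <- function(center, start_pos, strand) {
  ifelse(strand == "+", center - start_pos, start_pos - center)
}

#' Classify PBSs into context Types I/II/III
#'
#' Type I: the PBS interval overlaps (>= 1 bp) a sense IG region. Type II:
#' not Type I, and the PBS center lies within the strand-aware window
#' `[start + window[1], start + window[2]]` of some gene's start codon
#' (default 200 bp upstream to 50 bp downstream). Type III: everything else.
#' The nearest start codon (by absolute signed distance; for Type I restricted
#' to genes whose start abuts the overlapped sense IG, for Type II to genes
#' whose window contains the center) and its signed distance are reported;
#' negative distances are upstream of the start.
#'
#' @param pbss PBS data frame from [group_hits()] (needs `pbs_id`, `contig`,
#'   `start`, `end`, `center`).
#' @param ig_regions IG data frame from [compute_intergenic()].
#' @param annotations Annotation data frame.
#' @param window Length-2 numeric, offsets of the start-codon zone in gene
#'   coordinates (default `c(-200, 50)`).
#' @return Data frame: `pbs_id`, `context_type`, `nearest_start_gene`,
#'   `second_gene` (other abutting-start flank of a shared diverging IG, else
#'   `NA`), `distance_center_to_start`, `overlapped_ig`.
#' @export
classify_pbs <- function(pbss, ig_regions, annotations, window = c(-200, 50)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  n <- nrow(pbss)
  res <- data.frame(
    pbs_id = pbss$pbs_id,
    context_type = character(n),
    nearest_start_gene = NA_character_,
    second_gene = NA_character_,
    distance_center_to_start = NA_integer_,
    overlapped_ig = NA_character_,
    stringsAsFactors = FALSE
  )
  ann_start <- gene_start_pos(annotations)
  # strand-aware genomic zone around each start codon
  zone_lo <- ifelse(annotations$strand == "+",
                    ann_start + window[1], ann_start - window[2])
  zone_hi <- ifelse(annotations$strand == "+",
                    ann_start + window[2], ann_start - window[1])
  sense_ig <- ig_regions[ig_regions$is_sense, , drop = FALSE]
  for (i in seq_len(n)) {
    ctg <- pbss$contig[i]
    s <- pbss$start[i]; e <- pbss$end[i]; cen <- pbss$center[i]
    a_idx <- which(annotations$contig == ctg)
    ig_i <- sense_ig[sense_ig$contig == ctg & sense_ig$start <= e &
                       sense_ig$end >= s, , drop = FALSE]
    if (nrow(ig_i)) {
      res$context_type[i] <- "I"
      # pick the sense IG with the largest overlap
      ovw <- pmin(ig_i$end, e) - pmax(ig_i$start, s) + 1L
      ig_best <- ig_i[which.max(ovw), , drop = FALSE]
      res$overlapped_ig[i] <- ig_best$ig_id
      flanks <- character(0)
      if (!is.na(ig_best$left_gene)) {
        li <- a_idx[annotations$gene_id[a_idx] == ig_best$left_gene]
        if (length(li) && annotations$strand[li] == "-") flanks <- c(flanks, ig_best$left_gene)
      }
      if (!is.na(ig_best$right_gene)) {
        ri <- a_idx[annotations$gene_id[a_idx] == ig_best$right_gene]
        if (length(ri) && annotations$strand[ri] == "+") flanks <- c(flanks, ig_best$right_gene)
      }
      cand <- a_idx[annotations$gene_id[a_idx] %in% flanks]
      if (!length(cand)) cand <- a_idx
      if (length(cand)) {
        d <- signed_distance(cen, ann_start[cand], annotations$strand[cand])
        best <- which.min(abs(d))
        res$nearest_start_gene[i] <- annotations$gene_id[cand[best]]
        res$distance_center_to_start[i] <- as.integer(d[best])
        if (length(cand) > 1L) {
          others <- annotations$gene_id[cand[-best]]
          res$second_gene[i] <- others[1L]
        }
      }
    } else {
      in_zone <- a_idx[zone_lo[a_idx] <= cen & zone_hi[a_idx] >= cen]
      if (length(in_zone)) {
        res$context_type[i] <- "II"
        d <- signed_distance(cen, ann_start[in_zone],
                             annotations$strand[in_zone])
        best <- which.min(abs(d))
        res$nearest_start_gene[i] <- annotations$gene_id[in_zone[best]]
        res$distance_center_to_start[i] <- as.integer(d[best])
      } else {
        res$context_type[i] <- "III"
        if (length(a_idx)) {
          d <- signed_distance(cen, ann_start[a_idx],
                               annotations$strand[a_idx])
          best <- which.min(abs(d))
          res$nearest_start_gene[i] <- annotations$gene_id[a_idx[best]]
          res$distance_center_to_start[i] <- as.integer(d[best])
        }
      }
    }
  }
  res
}

#' Total bases of the start-codon zones ("250 bp zone") and of IG regions
#'
#' The 250 bp zone of a gene is the strand-aware window
#' `[start + window[1], start + window[2]]`, clipped to the contig;
#' overlapping zones are unioned before totalling.
#'
#' @inheritParams classify_pbs
#' @param contig_lengths Named vector of contig lengths.
#' @return List with `tIG` (total intergenic bases), `t250Z` (total zone
#'   bases) and `genome_length`.
#' @export
context_denominators <- function(annotations, contig_lengths,
                                 window = c(-200, 50)) {
  ig <- compute_intergenic(annotations, contig_lengths)
  tIG <- sum(ig$end - ig$start + 1L)
  ann_start <- gene_start_pos(annotations)
  zone_lo <- ifelse(annotations$strand == "+",
                    ann_start + window[1], ann_start - window[2])
  zone_hi <- ifelse(annotations$strand == "+",
                    ann_start + window[2], ann_start - window[1])
  t250Z <- 0
  for (ctg in names(contig_lengths)) {
    idx <- which(annotations$contig == ctg)
    if (!length(idx)) next
    lo <- pmax(zone_lo[idx], 1)
    hi <- pmin(zone_hi[idx], contig_lengths[[ctg]])
    keep <- lo <= hi
    if (!any(keep)) next
    red <- IRanges::reduce(IRanges::IRanges(lo[keep], hi[keep]))
    t250Z <- t250Z + sum(IRanges::width(red))
  }
  list(tIG = tIG, t250Z = t250Z, genome_length = sum(unlist(contig_lengths)))
}

#' PBS density per megabase by context type
#'
#' Densities divide the PBS count of each subset by the bases of the genome
#' available to that subset: Type I by total intergenic bases `tIG`, Type II
#' by `t250Z - tIG` (zone bases outside IG regions), Type III by
#' `genome_length - t250Z`; the three denominators always sum to the genome
#' length. A zero denominator yields `NA`, not infinity.
#'
#' @param counts Named numeric vector (`I`, `II`, `III`) or a matrix with
#'   rows `I`, `II`, `III` (e.g. type x set-label counts).
#' @param genome_length Total genome bases.
#' @param tIG Total intergenic bases.
#' @param t250Z Total unioned start-codon-zone bases.
#' @return Data frame with `type`, denominator `bases`, one count/density
#'   column pair per input column.
#' @export
density_by_type <- function(counts, genome_length, tIG, t250Z) {
  stopifnot(tIG <= genome_length, t250Z <= genome_length)
  denom <- c(I = tIG, II = t250Z - tIG, III = genome_length - t250Z)
  if (is.null(dim(counts))) counts <- cbind(count = counts[c("I", "II", "III")])
  counts <- counts[c("I", "II", "III"), , drop = FALSE]
  out <- data.frame(type = c("I", "II", "III"), bases = unname(denom))
  for (j in seq_len(ncol(counts))) {
    nm <- colnames(counts)[j]
    dens <- ifelse(denom > 0, counts[, j] / denom * 1e6, NA_real_)
    out[[paste0("n_", nm)]] <- unname(counts[, j])
    out[[paste0("density_", nm)]] <- unname(dens)
  }
  rownames(out) <- NULL
  out
}

#' Select candidate binding sites
#'
#' All Type I PBSs are selected; a Type II PBS is selected only if at least
#' one sigma-70 promoter prediction fell inside its flanked window (the PBS
#' plus 100 bp on each side by default, matching the promoter-prediction
#' input); Type III PBSs are never selected.
#'
#' @param context_calls Data frame from [classify_pbs()].
#' @param promoter_predictions Data frame of promoter predictions carrying a
#'   `pbs_id` column (one row per prediction inside that PBS's window), e.g.
#'   from [predict_pbs_promoters()]. May be empty.
#' @return Character vector of selected `pbs_id`s.
#' @export
select_candidates <- function(context_calls, promoter_predictions) {
  with_prom <- unique(as.character(promoter_predictions$pbs_id))
  sel <- context_calls$context_type == "I" |
    (context_calls$context_type == "II" & context_calls$pbs_id %in% with_prom)
  context_calls$pbs_id[sel]
}
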