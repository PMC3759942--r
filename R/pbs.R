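# Merging per-model hits into unique predicted binding sites (PBSs).
#
# A PBS is a fragment of the genome covered by one or more model hits on
# either strand; hits overlapping by at least 1 bp are merged by single
# linkage, strand ignored.

#' Group overlapping hits into predicted binding sites
#'
#' Single-linkage merging of hits that share at least one base pair on either
#' strand, per contig. Each merge is one PBS; its interval is the union of the
#' member hit intervals, its set labels the union of the members' set labels
#' (A/B models are the SP set, C/D the MP set, E the LP set).
#'
#' @param hits Hit data frame from [scan_genome()] (columns `model_id`,
#'   `set_label`, `contig`, `start`, `end`, `strand`, `score`).
#' @return Data frame of PBSs ordered by (contig, start): `pbs_id`, `contig`,
#'   `start`, `end`, `center` (floor of the interval midpoint), `set_labels`
#'   (comma-joined, sorted), `model_ids`, `n_hits`, `best_score`, plus a
#'   `member_hits` list-column of the member hit rows.
#' @export
group_hits <- function(hits) {
  empty <- data.frame(
    pbs_id = character(), contig = character(), start = integer(),
    end = integer(), center = integer(), set_labels = character(),
    model_ids = character(), n_hits = integer(), best_score = numeric(),
    stringsAsFactors = FALSE
  )
  if (is.null(hits) || nrow(hits) == 0L) {
    empty$member_hits <- list()
    return(empty)
  }
  stopifnot(all(c("model_id", "set_label", "contig", "start", "end") %in%
                  names(hits)))
  pieces <- list()
  for (ctg in sort(unique(hits$contig))) {
    h <- hits[hits$contig == ctg, , drop = FALSE]
    ir <- IRanges::IRanges(start = h$start, end = h$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)  # >=1 bp shared
    ov <- IRanges::findOverlaps(ir, merged)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    for (g in seq_along(merged)) {
      members <- h[grp == g, , drop = FALSE]
      s <- IRanges::start(merged)[g]
      e <- IRanges::end(merged)[g]
      pieces[[length(pieces) + 1L]] <- list(
        contig = ctg, start = s, end = e,
        center = as.integer(floor((s + e) / 2)),
        set_labels = paste(sort(unique(members$set_label)), collapse = ","),
        model_ids = paste(sort(unique(members$model_id)), collapse = ","),
        n_hits = nrow(members),
        best_score = max(members$score),
        member_hits = members
      )
    }
  }
  ord <- order(vapply(pieces, `[[`, "", "contig"),
               vapply(pieces, `[[`, 0, "start"))
  pieces <- pieces[ord]
  pbs <- data.frame(
    pbs_id = sprintf("PBS_%04d", seq_along(pieces)),
    contig = vapply(pieces, `[[`, "", "contig"),
    start = as.integer(vapply(pieces, `[[`, 0, "start")),
    end = as.integer(vapply(pieces, `[[`, 0, "end")),
    center = as.integer(vapply(pieces, `[[`, 0L, "center")),
    set_labels = vapply(pieces, `[[`, "", "set_labels"),
    model_ids = vapply(pieces, `[[`, "", "model_ids"),
    n_hits = as.integer(vapply(pieces, `[[`, 0L, "n_hits")),
    best_score = vapply(pieces, `[[`, 0, "best_score"),
    stringsAsFactors = FALSE
  )
  pbs$member_hits <- lapply(pieces, `[[`, "member_hits")
  pbs
}

#' Tally single/double/triple PBS site classes
#'
#' Counts PBSs by the number of distinct set labels they carry (single: one of
#' SP/MP/LP; double: two; triple: all three) and by the exact label
#' combination.
#'
#' @param pbss PBS data frame from [group_hits()].
#' @return List with `by_class` (named counts `single`, `double`, `triple`)
#'   and `by_combo` (counts per label combination string).
#' @export
tally_site_classes <- function(pbss) {
  nlab <- vapply(strsplit(pbss$set_labels, ",", fixed = TRUE), length, 0L)
  by_class <- c(
    single = sum(nlab == 1L),
    double = sum(nlab == 2L),
    triple = sum(nlab == 3L)
  )
  by_combo <- table(pbss$set_labels)
  stopifnot(sum(by_class) == nrow(pbss))
  list(by_class = by_class, by_combo = by_combo)
}

#' Write the PBS catalog as TSV and BED
#'
#' @param pbss PBS data frame from [group_hits()].
#' @param tsv,bed Output paths (`NULL` to skip either).
#' @return `pbss`, invisibly.
#' @export
write_pbs <- function(pbss, tsv = NULL, bed = NULL) {
  flat <- pbss[setdiff(names(pbss), "member_hits")]
  if (!is.null(tsv)) {
    utils::write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    bed6 <- data.frame(
      chrom = flat$contig, chromStart = flat$start - 1L, chromEnd = flat$end,
      name = flat$pbs_id, score = as.integer(round(flat$best_score * 100)),
      strand = "."
    )
    utils::write.table(bed6, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(pbss)
}
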