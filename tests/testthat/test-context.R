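mk_pbs <- function(start, end, id = "P1", contig = "chr") {
  data.frame(pbs_id = id, contig = contig, start = as.integer(start),
             end = as.integer(end),
             center = as.integer(floor((start + end) / 2)),
             stringsAsFactors = FALSE)
}

test_that("senseness follows the flanking start-codon rule", {
  ig <- compute_intergenic(tiny_annotation(), tiny_contig_lengths)
  # [1,200]: right flank g1 is "-", so no start abuts; left is contig end
  # g1 "-" has its start at 700 abutting [701,900]
  expect_equal(nrow(ig), 4L)
  expect_equal(ig$start, c(1L, 701L, 1501L, 2301L))
  expect_equal(ig$is_sense, c(FALSE, TRUE, TRUE, FALSE))
  # diverging pair: both flanks' starts abut -> sense
  div <- data.frame(gene_id = c("a", "b"), contig = "chr",
                    start = c(101L, 501L), end = c(400L, 800L),
                    strand = c("-", "+"), product = NA,
                    stringsAsFactors = FALSE)
  igd <- compute_intergenic(div, c(chr = 1000L))
  expect_true(igd$is_sense[igd$start == 401L])
  # converging pair: gap lies between the stop codons -> not sense
  conv <- transform(div, strand = c("+", "-"))
  igc <- compute_intergenic(conv, c(chr = 1000L))
  expect_false(igc$is_sense[igc$start == 401L])
  # tandem pair: the downstream gene's start abuts -> sense
  tand <- transform(div, strand = c("+", "+"))
  igt <- compute_intergenic(tand, c(chr = 1000L))
  expect_true(igt$is_sense[igt$start == 401L])
  # overlapping CDS are rejected with a diagnostic
  bad <- transform(div, end = c(600L, 800L))
  expect_error(compute_intergenic(bad, c(chr = 1000L)), "overlapping CDS")
  expect_error(compute_intergenic(transform(div, end = c(400L, 2000L)),
                                  c(chr = 1000L)), "outside contig")
})

test_that("PBSs classify into Types I/II/III by overlap and center rules", {
  ann <- tiny_annotation()
  ig <- compute_intergenic(ann, tiny_contig_lengths)
  # fully inside the diverging sense IG [701,900]
  c1 <- classify_pbs(mk_pbs(750, 780), ig, ann)
  expect_equal(c1$context_type, "I")
  expect_equal(c1$overlapped_ig, ig$ig_id[ig$start == 701L])
  # 1-bp overlap with a sense IG is enough
  expect_equal(classify_pbs(mk_pbs(690, 701), ig, ann)$context_type, "I")
  # center 150 bp upstream of a start codon but inside the upstream gene's
  # CDS (tandem pair with a 50-bp gap) -> Type II by the center rule
  tand <- data.frame(gene_id = c("t1", "t2"), contig = "chr",
                     start = c(101L, 851L), end = c(800L, 1600L),
                     strand = "+", product = NA, stringsAsFactors = FALSE)
  ig_t <- compute_intergenic(tand, c(chr = 2000L))
  c2 <- classify_pbs(mk_pbs(686, 716), ig_t, tand)  # center 701, in t1 CDS
  expect_equal(c2$context_type, "II")
  expect_equal(c2$nearest_start_gene, "t2")
  expect_equal(c2$distance_center_to_start, 701L - 851L)
  # deep inside a CDS, > 200 bp from any start -> Type III
  c3 <- classify_pbs(mk_pbs(1150, 1180), ig, ann)
  expect_equal(c3$context_type, "III")
  # downstream tolerance: center 40 bp into g2's CDS from its start
  c4 <- classify_pbs(mk_pbs(926, 956), ig, ann)   # center 941, start 901
  expect_equal(c4$context_type, "II")
  expect_equal(c4$distance_center_to_start, 40L)
})

test_that("strand-aware distances are negative upstream of the start", {
  ann <- tiny_annotation()
  ig <- compute_intergenic(ann, tiny_contig_lengths)
  # PBS in the diverging IG: g1 (-) start at 700, g2 (+) start at 901
  cc <- classify_pbs(mk_pbs(740, 760), ig, ann)   # center 750
  expect_equal(cc$nearest_start_gene, "g1")
  expect_equal(cc$distance_center_to_start, 700L - 750L)  # upstream of g1
  expect_equal(cc$second_gene, "g2")
  cc2 <- classify_pbs(mk_pbs(860, 880), ig, ann)  # center 870, nearer g2
  expect_equal(cc2$nearest_start_gene, "g2")
  expect_equal(cc2$distance_center_to_start, 870L - 901L)
})

test_that("type assignment partitions random PBS sets", {
  set.seed(23)
  for (rep in 1:5) {
    ann <- random_annotation(12, 4000L, seed = rep)
    ig <- compute_intergenic(ann, c(chr = 4000L))
    starts <- sample.int(3950, 60)
    pbs <- data.frame(pbs_id = sprintf("P%03d", seq_along(starts)),
                      contig = "chr", start = starts,
                      end = pmin(starts + 17L, 4000L),
                      center = as.integer(floor((starts + pmin(starts + 17L,
                                                               4000L)) / 2)),
                      stringsAsFactors = FALSE)
    cc <- classify_pbs(pbs, ig, ann)
    expect_true(all(cc$context_type %in% c("I", "II", "III")))
    expect_equal(nrow(cc), nrow(pbs))
  }
})

test_that("classification is invariant under genome mirroring", {
  ann <- tiny_annotation()
  L <- tiny_contig_lengths[["chr"]]
  ig <- compute_intergenic(ann, tiny_contig_lengths)
  mirror_ann <- data.frame(
    gene_id = ann$gene_id, contig = "chr",
    start = L - ann$end + 1L, end = L - ann$start + 1L,
    strand = ifelse(ann$strand == "+", "-", "+"),
    product = ann$product, stringsAsFactors = FALSE
  )
  mig <- compute_intergenic(mirror_ann, tiny_contig_lengths)
  set.seed(9)
  starts <- sample.int(L - 30L, 40)
  for (s in starts) {
    p <- mk_pbs(s, s + 20L)
    pm_start <- L - (s + 20L) + 1L
    pm <- mk_pbs(pm_start, pm_start + 20L)
    # centers of even-width intervals shift by one under mirroring; use the
    # exact mirrored center to keep the comparison strict
    pm$center <- L - p$center + 1L
    expect_equal(classify_pbs(p, ig, ann)$context_type,
                 classify_pbs(pm, mig, mirror_ann)$context_type,
                 info = s)
  }
})

test_that("density denominators follow the subset formulas and sum to the genome", {
  d <- density_by_type(c(I = 2, II = 0, III = 5), genome_length = 10000,
                       tIG = 1000, t250Z = 4000)
  expect_equal(d$bases, c(1000, 3000, 6000))
  expect_equal(sum(d$bases), 10000)
  expect_equal(d$density_count[1], 2000)   # 2 per kb = 2000 per Mb
  expect_equal(d$density_count[2], 0)
  # zero denominator reported as NA, not infinity
  d0 <- density_by_type(c(I = 2, II = 1, III = 0), genome_length = 4000,
                        tIG = 1000, t250Z = 4000)
  expect_true(is.na(d0$density_count[3]))
  expect_false(any(is.infinite(unlist(d0[-1]))))
})

test_that("denominator components are computed from the annotation", {
  ann <- tiny_annotation()
  d <- context_denominators(ann, tiny_contig_lengths)
  expect_equal(d$tIG, 200L + 200L + 200L + 700L)
  expect_equal(d$genome_length, 3000L)
  # zones: g1 (-): [650,900]; g2 (+): [701,951]; g3 (+): [1501,1751]
  # union: [650,951] + [1501,1751] = 302 + 251
  expect_equal(d$t250Z, 553L)
  expect_equal(d$tIG + (d$t250Z - d$tIG) + (d$genome_length - d$t250Z),
               d$genome_length)
})

test_that("candidate selection keeps Type I, gates Type II, drops Type III", {
  calls <- data.frame(
    pbs_id = c("P1", "P2", "P3", "P4"),
    context_type = c("I", "II", "II", "III"),
    stringsAsFactors = FALSE
  )
  proms <- data.frame(pbs_id = c("P2", "P4"))   # P4 is Type III anyway
  sel <- select_candidates(calls, proms)
  expect_setequal(sel, c("P1", "P2"))
  # Type I needs no promoter; Type II without one is rejected
  expect_false("P3" %in% sel)
  expect_false("P4" %in% sel)
  sel_none <- select_candidates(calls, proms[0, , drop = FALSE])
  expect_identical(sel_none, "P1")
})
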