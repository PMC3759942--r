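small_config <- function(seed = 1L, ...) {
  simulation_config(
    seed = seed, genome_length = 30000L,
    plants = data.frame(
      template_id = c("MP18", "SP13", "LP30"),
      context = c("sense_IG", "coding", "convergent_IG"),
      count = c(3L, 2L, 2L), sharpness = 1, stringsAsFactors = FALSE),
    ...)
}

test_that("simulated chromosomes honour length, GC and annotation bounds", {
  sim <- simulate_genome(simulation_config(seed = 7,
                                           genome_length = 50000L))
  expect_equal(nchar(sim$genome[[1]]), 50000L)
  chars <- strsplit(sim$genome[[1]], "")[[1]]
  expect_lt(abs(mean(chars %in% c("C", "G")) - 0.58), 0.01)
  a <- sim$annotations
  expect_true(all(a$start >= 1 & a$end <= 50000))
  a <- a[order(a$start), ]
  expect_true(all(a$start[-1] > a$end[-nrow(a)]))   # non-overlapping CDS
  # both strands and all three arrangements occur
  expect_setequal(unique(a$strand), c("+", "-"))
  pair <- paste0(a$strand[-nrow(a)], a$strand[-1])
  expect_true(all(c("-+", "+-") %in% pair))   # diverging and converging
  expect_true(any(pair %in% c("++", "--")))   # tandem
})

test_that("planted instances match their template at fixed positions", {
  sim <- simulate_genome(small_config(seed = 3))
  tpls <- builtin_templates()
  expect_equal(nrow(sim$truth), 7L)   # sum of plant counts
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    sub <- substr(sim$genome[[tr$contig]], tr$start, tr$end)
    if (tr$strand == "-") sub <- revcomp(sub)
    chars <- strsplit(tpls[[tr$template_id]]$pattern, "")[[1]]
    fixed <- chars %in% c("A", "C", "G", "T")
    expect_identical(strsplit(sub, "")[[1]][fixed], chars[fixed],
                     info = tr$instance_id)
  }
})

test_that("truth context labels agree with the classification rules", {
  for (seed in 1:3) {
    sim <- simulate_genome(small_config(seed = seed))
    expected <- c(sense_IG = "I", coding = "III", convergent_IG = "III")
    expect_identical(sim$truth$expected_type,
                     unname(expected[sim$truth$context]))
    # and re-deriving types from the planted intervals reproduces the table
    pseudo <- data.frame(
      pbs_id = sim$truth$instance_id, contig = sim$truth$contig,
      start = sim$truth$start, end = sim$truth$end,
      center = as.integer(floor((sim$truth$start + sim$truth$end) / 2)),
      stringsAsFactors = FALSE)
    calls <- classify_pbs(pseudo, sim$ig_regions, sim$annotations)
    expect_identical(calls$context_type, sim$truth$expected_type)
  }
})

test_that("simulation output is byte-reproducible and seed-sensitive", {
  s1 <- simulate_genome(small_config(seed = 11))
  s2 <- simulate_genome(small_config(seed = 11))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genome(small_config(seed = 12))
  expect_false(identical(s1$genome, s3$genome))
  # file outputs byte-identical across runs
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(s1, d1)
  p2 <- write_simulation(s2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
  }
  # round trip through FASTA/GFF3
  expect_identical(read_genome(p1[["fasta"]]), s1$genome)
  ann <- read_annotation(p1[["gff"]])
  expect_equal(ann$start, s1$annotations$start)
  expect_equal(ann$strand, s1$annotations$strand)
})

test_that("infeasible packing is rejected with a diagnostic", {
  expect_error(
    simulate_genome(simulation_config(seed = 1, genome_length = 5000L,
                                      n_genes = 50L)),
    "infeasible packing")
  expect_error(
    simulate_genome(simulation_config(
      seed = 1, genome_length = 2500L, n_genes = 2L,
      plants = data.frame(template_id = "LP30", context = "sense_IG",
                          count = 50L, sharpness = 1))),
    "infeasible packing")
})

test_that("recovery benchmarking scores sensitivity, merges and accuracy", {
  sim <- simulate_genome(small_config(seed = 5))
  truth <- sim$truth
  # empty PBS list -> zero sensitivity
  empty <- group_hits(NULL)
  b0 <- benchmark_recovery(truth, empty, data.frame(pbs_id = character(),
                                                    context_type = character()))
  expect_equal(b0$sensitivity, 0)
  # PBSs exactly equal to truth intervals with the true context rules
  pbs <- data.frame(pbs_id = sprintf("PBS_%04d", seq_len(nrow(truth))),
                    contig = truth$contig, start = truth$start,
                    end = truth$end,
                    center = as.integer(floor((truth$start + truth$end) / 2)),
                    stringsAsFactors = FALSE)
  calls <- classify_pbs(pbs, sim$ig_regions, sim$annotations)
  b1 <- benchmark_recovery(truth, pbs, calls)
  expect_equal(b1$sensitivity, 1)
  expect_equal(b1$classification_accuracy, 1)
  expect_equal(b1$false_merges, 0L)
  expect_equal(b1$false_pbs, 0L)
  # a PBS spanning two disjoint plants counts as a false merge
  two <- truth[1:2, ]
  span <- data.frame(pbs_id = "PBS_0001", contig = two$contig[1],
                     start = min(two$start), end = max(two$end),
                     center = as.integer(floor((min(two$start) +
                                                  max(two$end)) / 2)),
                     stringsAsFactors = FALSE)
  calls2 <- classify_pbs(span, sim$ig_regions, sim$annotations)
  b2 <- benchmark_recovery(two, span, calls2)
  expect_equal(b2$false_merges, 1L)
})
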