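test_that("ZOOPS EM recovers planted palindrome instances exactly", {
  tpl <- builtin_templates()$MP18
  ps <- planted_set(tpl, n_seqs = 12, len = 120, seed = 101)
  m <- discover_motif(ps$seqs, width = 18, seed = 1)
  expect_s3_class(m, "motif_model")
  # consensus matches the template at all fixed positions (allowing the
  # reverse complement, which is equivalent for a dyad-symmetric motif)
  chars <- strsplit(tpl$pattern, "")[[1]]
  fixed <- chars %in% c("A", "C", "G", "T")
  dist_f <- sum(strsplit(m$consensus, "")[[1]][fixed] != chars[fixed])
  dist_r <- sum(strsplit(revcomp(m$consensus), "")[[1]][fixed] != chars[fixed])
  expect_lte(min(dist_f, dist_r), 1)
  # sites found at the planted offsets
  found <- m$sites$offset[match(names(ps$seqs), m$sites$sequence_id)]
  expect_gte(mean(found == ps$offsets, na.rm = TRUE), 0.9)
  # EM objective is monotone non-decreasing
  expect_true(all(diff(m$llr_trace) >= -1e-6 * pmax(1, abs(m$llr))))
})

test_that("EM result is invariant to input sequence order", {
  tpl <- builtin_templates()$MP18
  ps <- planted_set(tpl, n_seqs = 8, len = 80, seed = 103)
  m1 <- discover_motif(ps$seqs, width = 18, seed = 7)
  set.seed(42)
  perm <- sample(seq_along(ps$seqs))
  m2 <- discover_motif(ps$seqs[perm], width = 18, seed = 7)
  expect_equal(m1$emissions, m2$emissions, tolerance = 1e-9)
  expect_equal(m1$llr, m2$llr, tolerance = 1e-9)
  s1 <- m1$sites[order(m1$sites$sequence_id), c("sequence_id", "offset")]
  s2 <- m2$sites[order(m2$sites$sequence_id), c("sequence_id", "offset")]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
})

test_that("noise-free identical sites drive emissions to one-hot", {
  word <- "TGACAAGCTGTC"
  seqs <- rep(word, 6)
  m <- discover_motif(seqs, width = nchar(word), seed = 1)
  code <- afescan:::encode_dna(word)
  top <- vapply(seq_len(ncol(m$emissions)), function(j) {
    m$emissions[code[j], j]
  }, 0)
  # deviation from 1 bounded by the pseudocount mass
  expect_true(all(top > 1 - 4 * 0.25 / (6 + 1)))
})

test_that("exact score distribution matches exhaustive enumeration", {
  g <- 0.01
  for (w in 2:5) {
    pssm <- random_pssm(w, seed = 200 + w)
    d <- exact_score_distribution(pssm, granularity = g)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    ints <- round(pssm / g)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    sc <- apply(words, 1L, function(idx) sum(ints[cbind(idx, seq_len(w))]))
    bf <- tapply(rep(0.25^w, nrow(words)), sc, sum)
    expect_equal(d$support, as.integer(names(bf)))
    expect_equal(unname(d$prob), unname(as.numeric(bf)), tolerance = 1e-12)
  }
})

test_that("score distribution degenerate cases have closed forms", {
  # uniform PSSM (all zero scores) -> point mass at 0
  d0 <- exact_score_distribution(matrix(0, 4, 6,
                                        dimnames = list(c("A", "C", "G", "T"),
                                                        NULL)))
  expect_equal(d0$support, 0L)
  expect_equal(d0$prob, 1)
  expect_equal(score_pvalue(d0, 0), 1)
  # strict-max PSSM: P(score >= max) = product of argmax background probs,
  # with the maximum taken on the discretised score lattice
  pssm <- random_pssm(4, seed = 300)
  g <- 0.01
  d <- exact_score_distribution(pssm, granularity = g)
  max_int <- sum(apply(round(pssm / g), 2, max))
  expect_equal(sum(d$prob[d$support >= max_int]), 0.25^4,
               tolerance = 1e-12)
  expect_equal(max(d$support), max_int)
})

test_that("the intergenic rescan ranks a planted instance first", {
  set.seed(55)
  db <- vapply(1:50, function(i) random_dna(150), "")
  names(db) <- sprintf("ig%03d", 1:50)
  tpl <- builtin_templates()$MP18
  db[["ig025"]] <- splice_at(db[["ig025"]], template_instance(tpl), 60L)
  pm <- build_profile(enumerate_variants(tpl))
  db <- c(db, igshort = "ACGT")   # shorter than the motif: skipped
  expect_message(occ <- mast_scan(pm$log_odds, db, evalue_cutoff = 10),
                 "skipping")
  expect_equal(occ$sequence_id[1], "ig025")
  expect_equal(occ$offset[1], 60L)
  # e-value is the sequence p-value scaled by the database size
  expect_equal(occ$evalue, occ$sequence_pvalue * 51)
  # cutoff 0 returns nothing
  expect_equal(nrow(mast_scan(pm$log_odds, db, evalue_cutoff = 0)), 0L)
})

test_that("rescanning the reverse-complemented database is strand-symmetric", {
  set.seed(57)
  db <- vapply(1:20, function(i) random_dna(100), "")
  names(db) <- sprintf("ig%03d", 1:20)
  db[["ig007"]] <- splice_at(db[["ig007"]],
                             template_instance(builtin_templates()$SP13), 40L)
  pm <- build_profile(enumerate_variants(builtin_templates()$SP13))
  occ_f <- mast_scan(pm$log_odds, db, evalue_cutoff = 50)
  occ_r <- mast_scan(pm$log_odds, setNames(revcomp(db), names(db)),
                     evalue_cutoff = 50)
  occ_r <- occ_r[match(occ_f$sequence_id, occ_r$sequence_id), ]
  expect_equal(occ_f$evalue, occ_r$evalue, tolerance = 1e-9)
  expect_equal(occ_f$score, occ_r$score, tolerance = 1e-9)
})

test_that("consensus and information content summarise aligned sites", {
  # identical sites -> 2 bits everywhere
  cl <- consensus_and_logo(rep("TGACA", 4))
  expect_equal(cl$consensus, "TGACA")
  expect_equal(cl$ic, rep(2, 5))
  # equal counts of all four bases -> 0 bits
  cl0 <- consensus_and_logo(c("A", "C", "G", "T"))
  expect_equal(cl0$ic, 0)
  expect_equal(cl0$consensus, "N")
  # column {A:3, C:1}: consensus A, IC = 2 + .75 log2 .75 + .25 log2 .25
  cl1 <- consensus_and_logo(c("A", "A", "A", "C"))
  expect_equal(cl1$consensus, "A")
  expect_equal(cl1$ic, 2 + 0.75 * log2(0.75) + 0.25 * log2(0.25),
               tolerance = 1e-12)
  # two-way tie -> IUPAC code
  cl2 <- consensus_and_logo(c("AG", "AG", "GG", "GG"))
  expect_equal(cl2$consensus, "RG")
  expect_error(consensus_and_logo(c("AA", "A")), "equal-length")
})

test_that("motif files round-trip through the MEME minimal format", {
  tpl <- builtin_templates()$SP13
  ps <- planted_set(tpl, n_seqs = 6, len = 60, seed = 111)
  m <- discover_motif(ps$seqs, width = 13, seed = 3)
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_motif(m, path)
  lines <- readLines(path)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 13",
                        lines)))
  mat_lines <- grep("^ [0-9]", lines, value = TRUE)
  expect_length(mat_lines, 13L)
  probs <- do.call(rbind, lapply(strsplit(trimws(mat_lines), "\\s+"),
                                 as.numeric))
  expect_equal(rowSums(probs), rep(1, 13), tolerance = 1e-4)
})
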