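test_that("a cDNA identical to the genomic sequence maps as one exon", {
  seq <- random_dna(150L, seed = 3)
  m <- align_spliced(nuc_record("c", seq), nuc_record("g", seq))
  expect_equal(nrow(m$exons), 1L)
  expect_equal(nrow(m$introns), 0L)
  expect_equal(m$identity, 1)
  expect_equal(unname(m$exons[1L, ]), c(0L, 150L))
})

test_that("a single planted GT-AG intron is recovered exactly", {
  # E1 + 40 nt GT..AG intron + E2, exons 60 nt each
  g <- generate_gene(gene_spec(exon_count = 2,
                               exon_len_range = c(60L, 60L),
                               intron_len_range = c(40L, 40L), seed = 11))
  m <- align_spliced(g$cdna, g$genomic)
  expect_equal(unname(m$exons),
               matrix(c(0L, 60L, 100L, 160L), 2L, byrow = TRUE))
  expect_equal(unname(m$introns), matrix(c(60L, 100L), 1L))
  expect_equal(m$identity, 1)
})

test_that("the aligner matches the exhaustive enumeration oracle", {
  p <- align_params()
  for (seed in 1:12) {
    set.seed(seed * 100)
    n_int <- seed %% 3L                   # 0, 1 or 2 introns
    exlen <- sample(14:22, n_int + 1L, replace = TRUE)
    g <- generate_gene(gene_spec(
      exon_count = n_int + 1L,
      exon_len_range = range(exlen),
      intron_len_range = c(25L, 32L), seed = seed))
    if (nchar(g$genomic$seq) > 120L) next
    m <- align_spliced(g$cdna, g$genomic, p)
    expect_equal(m$score,
                 oracle_best_score(g$cdna$seq, g$genomic$seq, p,
                                   max_introns = 2L),
                 info = paste("seed", seed))
  }
  # and on larger DP-path instances with mutations
  for (seed in 21:26) {
    g <- generate_gene(gene_spec(exon_count = 2,
                                 exon_len_range = c(25L, 40L),
                                 intron_len_range = c(25L, 40L),
                                 mutation_rate = 0.02, seed = seed))
    m <- align_spliced(g$cdna, g$genomic, align_params(min_identity = 0.8))
    expect_equal(m$score,
                 oracle_best_score(g$cdna$seq, g$genomic$seq,
                                   max_introns = 2L),
                 info = paste("seed", seed))
  }
})

test_that("exon concatenation reproduces the cDNA at identity 1", {
  for (seed in 1:5) {
    g <- generate_gene(gene_spec(exon_count = 5, seed = seed))
    m <- align_spliced(g$cdna, g$genomic)
    expect_equal(m$identity, 1)
    spliced <- paste(substring(g$genomic$seq, m$exons[, 1L] + 1L,
                               m$exons[, 2L]), collapse = "")
    expect_equal(spliced, g$cdna$seq)
  }
})

test_that("multi-exon genes are recovered by the anchoring engine", {
  # default spec sizes put these on the anchor path (combined > 2 kb)
  for (seed in 31:40) {
    g <- generate_gene(gene_spec(exon_count = 9, mutation_rate = 0.02,
                                 seed = seed))
    m <- refine_boundaries(align_spliced(g$cdna, g$genomic),
                           g$genomic, g$cdna)
    expect_equal(unname(m$exons), unname(g$truth$exons),
                 info = paste("seed", seed))
  }
})

test_that("splice audit reports donors, acceptors and canonical flags", {
  # genomic: exon1 (10) + intron GTAAG...CAG (20) + exon2 (10)
  e1 <- "ACCTGACTAC"; e2 <- "TTGACCATGG"
  intron1 <- paste0("GTAAG", strrep("C", 12), "CAG")
  g1 <- nuc_record("g", paste0(e1, intron1, e2))
  model <- make_model(c(0, 10, 30, 40))
  audit <- audit_splice_sites(model, g1)
  expect_equal(audit$donor, "GT")
  expect_equal(audit$acceptor, "AG")
  expect_true(audit$canonical)
  expect_true(attr(audit, "all_canonical"))

  intron2 <- paste0("CTAC", strrep("G", 14), "AC")
  g2 <- nuc_record("g", paste0(e1, intron2, e2))
  audit2 <- audit_splice_sites(model, g2)
  expect_equal(audit2$donor, "CT")
  expect_equal(audit2$acceptor, "AC")
  expect_false(audit2$canonical)
  expect_false(attr(audit2, "all_canonical"))

  bad <- make_model(c(0, 10, 45, 50))      # intron end beyond genomic
  expect_error(audit_splice_sites(bad, g1), "out of genomic bounds")

  all_can <- generate_gene(gene_spec(exon_count = 9, seed = 5))
  m <- align_spliced(all_can$cdna, all_can$genomic)
  expect_true(attr(audit_splice_sites(m, all_can$genomic),
                   "all_canonical"))
})

test_that("boundary refinement restores canonical junctions and never
           lowers the score", {
  for (seed in 41:48) {
    g <- generate_gene(gene_spec(exon_count = 4, seed = seed))
    m <- align_spliced(g$cdna, g$genomic)
    ref <- refine_boundaries(m, g$genomic, g$cdna)
    expect_gte(ref$score, m$score)
    # fixed point: refining an already-optimal model changes nothing
    ref2 <- refine_boundaries(ref, g$genomic, g$cdna)
    expect_equal(ref2$exons, ref$exons)
    expect_equal(ref2$score, ref$score)
  }
  # nudge a junction off the planted position; refinement must restore it
  g <- generate_gene(gene_spec(exon_count = 3, seed = 51))
  m <- align_spliced(g$cdna, g$genomic)
  shifted <- m
  shifted$cdna_exons[1L, 2L] <- shifted$cdna_exons[1L, 2L] - 2L
  shifted$exons[1L, 2L] <- shifted$exons[1L, 2L] - 2L
  shifted$cdna_exons[2L, 1L] <- shifted$cdna_exons[2L, 1L] - 2L
  shifted$exons[2L, 1L] <- shifted$exons[2L, 1L] - 2L
  fixed <- refine_boundaries(shifted, g$genomic, g$cdna)
  expect_equal(unname(fixed$exons), unname(g$truth$exons))
  expect_gte(fixed$score, m$score)
})

test_that("degenerate and failing inputs raise informative errors", {
  expect_error(align_spliced(nuc_record("c", strrep("A", 50)),
                             nuc_record("g", strrep("A", 20))),
               "longer than the genomic")
  expect_error(align_spliced(nuc_record("c", random_dna(60, 1)),
                             nuc_record("g", random_dna(200, 2))),
               "no spliced mapping")
})
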