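test_that("fixtures are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- gene_spec(exon_count = 5, mutation_rate = 0.01,
                    motif_plant = "type_I", seed = 99)
  p1 <- write_fixture(generate_gene(spec), d1)
  p2 <- write_fixture(generate_gene(spec), d2)
  for (nm in names(p1)) {
    expect_identical(readBin(p1[[nm]], "raw", file.size(p1[[nm]])),
                     readBin(p2[[nm]], "raw", file.size(p2[[nm]])),
                     info = nm)
  }
  # a different seed changes the sequences
  other <- generate_gene(gene_spec(exon_count = 5, mutation_rate = 0.01,
                                   motif_plant = "type_I", seed = 100))
  expect_false(identical(other$cdna$seq, generate_gene(spec)$cdna$seq))
})

test_that("a single-exon spec yields genomic identical to the cDNA", {
  g <- generate_gene(gene_spec(exon_count = 1, seed = 7))
  expect_identical(g$genomic$seq, g$cdna$seq)
  expect_equal(nrow(g$truth$introns), 0L)
})

test_that("nine-exon fixtures plant eight GT-AG introns", {
  g <- generate_gene(gene_spec(exon_count = 9, seed = 1))
  tr <- g$truth
  expect_equal(nrow(tr$exons), 9L)
  expect_equal(nrow(tr$introns), 8L)
  donors <- substring(g$genomic$seq, tr$introns[, 1L] + 1L,
                      tr$introns[, 1L] + 2L)
  acceptors <- substring(g$genomic$seq, tr$introns[, 2L] - 1L,
                         tr$introns[, 2L])
  expect_true(all(donors == "GT"))
  expect_true(all(acceptors == "AG"))
  # introns are exactly the gaps between consecutive exons
  expect_equal(tr$introns[, 1L], tr$exons[-9L, 2L])
  expect_equal(tr$introns[, 2L], tr$exons[-1L, 1L])
  # exon concatenation is the cDNA
  expect_equal(paste(substring(g$genomic$seq, tr$exons[, 1L] + 1L,
                               tr$exons[, 2L]), collapse = ""),
               g$cdna$seq)
})

test_that("non-canonical introns are produced on request", {
  g <- generate_gene(gene_spec(exon_count = 3,
                               non_canonical_fraction = 1, seed = 13))
  donors <- substring(g$genomic$seq, g$truth$introns[, 1L] + 1L,
                      g$truth$introns[, 1L] + 2L)
  expect_true(all(donors != "GT"))
  expect_false(all(g$truth$canonical))
})

test_that("the indel stress mode perturbs exon copies but stays
           deterministic", {
  spec <- gene_spec(exon_count = 3, indel_rate = 0.05, seed = 17)
  g <- generate_gene(spec)
  # genomic exon intervals follow the post-indel copy lengths
  expect_equal(max(g$truth$exons), nchar(g$genomic$seq))
  expect_false(nchar(g$genomic$seq) - sum(g$truth$introns[, 2L] -
                                            g$truth$introns[, 1L]) ==
                 nchar(g$cdna$seq) &&
                 identical(paste(substring(g$genomic$seq,
                                           g$truth$exons[, 1L] + 1L,
                                           g$truth$exons[, 2L]),
                                 collapse = ""), g$cdna$seq))
  expect_identical(generate_gene(spec)$genomic$seq, g$genomic$seq)
})

test_that("planted ORFs are found by the pipeline's own validators", {
  for (seed in 1:4) {
    g <- generate_gene(gene_spec(exon_count = 6,
                                 exon_len_range = c(100L, 160L),
                                 motif_plant = "type_II_III", seed = seed))
    orf <- find_orf(g$cdna)
    expect_equal(orf$start, g$truth$orf[1L])
    expect_equal(orf$end, g$truth$orf[2L])
    expect_equal(translate_orf(orf, g$cdna)$seq, g$protein$seq)
  }
})

test_that("infeasible motif-bearing specs are rejected", {
  expect_error(generate_gene(gene_spec(exon_count = 2,
                                       exon_len_range = c(40L, 60L),
                                       motif_plant = "type_I", seed = 1)),
               "infeasible")
  expect_error(gene_spec(exon_count = 3), "seed")
  expect_error(generate_protein_with_cld("type_I", length = 100L,
                                         seed = 1), ">= 150")
})

test_that("planted CLD features match the requested type", {
  for (seed in 1:10) {
    t1 <- generate_protein_with_cld("type_I", length = 200L, seed = seed)
    expect_true(t1$truth$upstream5 %in% c("F", "Y", "W"))
    expect_false(t1$truth$upstream4 %in% c("F", "Y", "W"))
    expect_equal(t1$truth$farm_form, "DDxxD")
    t23 <- generate_protein_with_cld("type_II_III", length = 200L,
                                     seed = seed)
    expect_true(t23$truth$upstream5 %in% c("A", "S", "G", "T", "C"))
    expect_true(t23$truth$upstream4 %in% c("A", "S", "G", "T", "C"))
    expect_equal(t23$truth$farm_form, "DDxxxxD")
  }
})

test_that("the crtE surrogate reproduces the published gene architecture", {
  loc <- synthetic_crte_locus(seed = 1)
  expect_equal(nchar(loc$cdna$seq), 1134L)
  expect_equal(nchar(loc$genomic$seq), 1722L)
  expect_equal(nchar(loc$protein$seq), 377L)
  expect_equal(nrow(loc$truth$exons), 9L)
  expect_equal(nrow(loc$truth$introns), 8L)
  expect_true(startsWith(loc$protein$seq, "MTEFYDNF"))
  expect_true(endsWith(loc$protein$seq, "NGTNDTH"))
  # cDNA termini follow the cloning primers (KpnI/BamHI tails removed)
  expect_true(startsWith(loc$cdna$seq, "ATGACGGAGTTCTACGACAACTTTC"))
  expect_true(endsWith(loc$cdna$seq, "CGAATGGTACAAACGATACTCACTGA"))
  expect_identical(synthetic_crte_locus(seed = 1)$genomic$seq,
                   loc$genomic$seq)
})
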