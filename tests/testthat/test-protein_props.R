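test_that("ORF finding handles minimal and nested cases", {
  orf <- find_orf(nuc_record("x", "ATGTAA"))
  expect_equal(c(orf$start, orf$end), c(0L, 6L))
  expect_equal(orf$length_nt, 6L)
  expect_true(orf$complete)

  # ORF in frame 2 overlapping an out-of-frame ATG
  orf2 <- find_orf(nuc_record("x", "CCATGAAATGAGG"))
  expect_equal(c(orf2$start, orf2$end), c(2L, 11L))

  expect_error(find_orf(nuc_record("x", "CCCCCCCC")), "no ORF")
  expect_error(find_orf(nuc_record("x", "ATGT")), "shorter than 6")
})

test_that("ORF finding agrees with the all-frames brute force", {
  for (seed in 1:40) {
    len <- 60L + (seed * 7L) %% 241L      # up to 300 nt
    seq <- random_dna(len, seed = seed + 500L)
    want <- oracle_longest_orf(seq)
    if (is.null(want)) {
      expect_error(find_orf(nuc_record("x", seq)), "no ORF")
    } else {
      got <- find_orf(nuc_record("x", seq))
      expect_equal(c(got$start, got$end), want, info = paste("seed", seed))
    }
  }
})

test_that("translation uses the standard code and drops the stop", {
  # core of the crtE forward cloning primer
  cdna <- nuc_record("c", "ATGACGGAGTTCTACGACAACTTTTGA")
  p <- translate_orf(find_orf(cdna), cdna)
  expect_equal(p$seq, "MTEFYDNF")

  tiny <- nuc_record("t", "ATGTAA")
  expect_equal(translate_orf(find_orf(tiny), tiny)$seq, "M")

  amb <- nuc_record("a", "ATGNNNTAA")
  orf <- list(start = 0L, end = 9L, frame = 0L, length_nt = 9L,
              complete = TRUE, cdna_id = "a")
  class(orf) <- "orf_call"
  expect_error(translate_orf(orf, amb), "ambiguous")
})

test_that("molecular weight is the average-mass sum plus one water", {
  expect_equal(round(molecular_weight("G"), 2), 75.07)
  expect_error(molecular_weight(""), "empty")
  # additivity: MW(a + b) = MW(a) + MW(b) - one water
  for (seed in 1:10) {
    a <- random_protein(5L + seed, seed)
    b <- random_protein(9L + seed, seed + 100L)
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 18.01524,
                 tolerance = 1e-9)
  }
})

test_that("molecular weight matches independent calculators", {
  # frozen reference values from the biopython ProtParam implementation
  cases <- list(list("MTEFYDNF", 1066.14),
                list("ACDEFGHIKLMNPQRSTVWY", 2395.7134),
                list("MKWVTFISLLFLFSSAYS", 2140.5405))
  for (cs in cases) {
    expect_equal(molecular_weight(cs[[1L]]), cs[[2L]], tolerance = 2e-5)
  }
  if (requireNamespace("seqinr", quietly = TRUE)) {
    for (seed in 1:5) {
      p <- random_protein(80L, seed + 300L)
      expect_equal(molecular_weight(p),
                   seqinr::pmw(strsplit(p, "")[[1L]]), tolerance = 1e-3)
    }
  }
})

test_that("net charge has the right limits and monotonicity", {
  p <- random_protein(60L, seed = 9)
  expect_gt(net_charge(p, 0), 0)
  expect_lt(net_charge(p, 14), 0)
  phs <- seq(0, 14, by = 0.5)
  qs <- vapply(phs, function(ph) net_charge(p, ph), numeric(1))
  expect_true(all(diff(qs) < 0))
})

test_that("pI bisection agrees with the dense grid oracle", {
  expect_equal(isoelectric_point("GG"), oracle_grid_pi("GG"),
               tolerance = 0.01)
  expect_lt(isoelectric_point("DDDDD"), isoelectric_point("KKKKK"))
  # self-consistency: the net charge at the reported pI is ~0
  p <- random_protein(120L, seed = 77)
  expect_lt(abs(net_charge(p, isoelectric_point(p))), 1e-4)
  for (seed in 1:30) {
    prot <- random_protein(30L + seed * 3L, seed = seed + 900L)
    expect_equal(isoelectric_point(prot), oracle_grid_pi(prot),
                 tolerance = 0.01, info = paste("seed", seed))
  }
})

test_that("pI matches the frozen ProtParam-style reference values", {
  # frozen from an independent Bjellqvist implementation, restricted to
  # peptides whose reported pI is a genuine zero-charge root (some
  # implementations clamp their search window near pH 4, which truncates
  # strongly acidic peptides)
  cases <- list(list("GG", 5.525),
                list("KKKKK", 10.602487),
                list("ACDEFGHIKLMNPQRSTVWY", 6.784552),
                list("MKWVTFISLLFLFSSAYS", 8.344739))
  for (cs in cases) {
    expect_equal(isoelectric_point(cs[[1L]]), cs[[2L]], tolerance = 0.01)
  }
})

test_that("protein stats bundle length, mass and pI consistently", {
  loc <- synthetic_crte_locus(seed = 1)
  st <- protein_stats(loc$protein)
  expect_equal(st$length, 377L)
  expect_equal(st$length, (find_orf(loc$cdna)$length_nt) / 3 - 1)
  expect_equal(sum(st$composition), 377L)
  expect_gt(st$mw_da, 0)
  expect_true(st$pi > 0 && st$pi < 14)
})
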