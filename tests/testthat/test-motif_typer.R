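test_that("proteins without aspartate-rich motifs yield no hits", {
  expect_length(scan_motifs(strrep("A", 200L)), 0L)
  # aspartates present but no DD..D pattern
  expect_length(scan_motifs(paste(rep("ADA", 70L), collapse = "")), 0L)
})

test_that("planted FARM/SARM pairs are found with form and position", {
  bg <- strsplit(random_protein(300L, seed = 42), "")[[1L]]
  bg[bg == "D"] <- "A"
  bg[71:77] <- strsplit("DDIQAAD", "")[[1L]]   # FARM at 0-based 70
  bg[221:225] <- strsplit("DDYLD", "")[[1L]]   # SARM at 0-based 220
  hits <- scan_motifs(paste(bg, collapse = ""))
  expect_length(hits, 2L)
  expect_equal(hits[[1L]]$kind, "FARM")
  expect_equal(hits[[1L]]$start, 70L)
  expect_equal(hits[[1L]]$farm_form, "DDxxxxD")
  expect_equal(hits[[1L]]$pattern, "DDIQAAD")
  expect_equal(hits[[2L]]$kind, "SARM")
  expect_equal(hits[[2L]]$start, 220L)
})

test_that("motif scan agrees with the brute-force enumeration", {
  for (seed in 1:25) {
    prot <- random_protein(150L + (seed * 13L) %% 200L, seed = seed + 70L)
    want <- oracle_scan(prot)
    got <- scan_motifs(prot)
    if (is.null(want)) {
      expect_length(got, 0L)
    } else {
      expect_equal(got[[1L]]$start, want$farm_start,
                   info = paste("seed", seed))
      expect_equal(got[[1L]]$farm_form, want$farm_form)
      expect_equal(got[[2L]]$start, want$sarm_start)
    }
  }
  # and on generator fixtures, where the truth is planted
  for (seed in 101:110) {
    plant <- if (seed %% 2L) "type_I" else "type_II_III"
    fx <- generate_protein_with_cld(plant, length = 250L, seed = seed)
    hits <- scan_motifs(fx$protein)
    expect_equal(hits[[1L]]$start, fx$truth$farm_start)
    expect_equal(hits[[1L]]$farm_form, fx$truth$farm_form)
    expect_equal(hits[[2L]]$start, fx$truth$sarm_start)
  }
})

test_that("CLD extraction returns the FARM plus five upstream residues", {
  prot <- paste0("AAAAAYAGSLDDVMD", strrep("A", 90L))
  farm <- list(kind = "FARM", start = 10L, end = 15L, pattern = "DDVMD",
               farm_form = "DDxxD")
  cld <- extract_cld(prot, farm)
  expect_equal(cld$sequence, "YAGSLDDVMD")
  expect_equal(cld$upstream5, "Y")
  expect_equal(cld$upstream4, "A")
  expect_equal(cld$start, 5L)

  farm5 <- list(kind = "FARM", start = 5L, end = 10L, pattern = "DDVMD",
                farm_form = "DDxxD")
  cld5 <- extract_cld(paste0("AGSLQDDVMD", strrep("A", 90L)), farm5)
  expect_equal(cld5$sequence, substr(paste0("AGSLQDDVMD"), 1L, 10L))
  expect_equal(cld5$start, 0L)

  farm4 <- list(kind = "FARM", start = 4L, end = 9L, pattern = "DDVMD",
                farm_form = "DDxxD")
  expect_error(extract_cld(prot, farm4), "too close")
})

test_that("the type rules classify CLD patterns as the field defines them", {
  panel <- read_panel(synthetic_panel_path())
  mk <- function(u5, u4, form) {
    pat <- if (form == "DDxxD") "DDVMD" else "DDIESAD"
    farm <- list(kind = "FARM", start = 10L, end = 10L + nchar(pat),
                 pattern = pat, farm_form = form)
    prot <- paste0("AAAAA", u5, u4, "AAA", pat, strrep("A", 100L))
    list(farm = farm, cld = extract_cld(prot, farm))
  }
  t1 <- mk("Y", "A", "DDxxD")
  expect_equal(classify_type(t1$farm, t1$cld, panel)$type, "I")
  # aromatic at -4 disqualifies type I
  t1b <- mk("Y", "F", "DDxxD")
  expect_equal(classify_type(t1b$farm, t1b$cld, panel)$type,
               "unclassified")
  # DDxxxxD + non-aromatic upstream cannot be typed without homology
  t23 <- mk("A", "S", "DDxxxxD")
  expect_error(classify_type(t23$farm, t23$cld, NULL), "panel required")
  call <- classify_type(t23$farm, t23$cld, panel)
  expect_true(call$type %in% c("II", "III"))
  expect_false(is.na(call$nearest_reference))
  # no FARM at all
  expect_equal(classify_type(NULL, NULL, panel)$type, "unclassified")
})

test_that("the crtE surrogate is classified as type III via CLD homology", {
  loc <- synthetic_crte_locus(seed = 1)
  hits <- scan_motifs(loc$protein)
  cld <- extract_cld(loc$protein, hits[[1L]])
  expect_equal(cld$upstream5, "A")
  expect_equal(cld$upstream4, "S")
  call <- classify_type(hits[[1L]], cld, read_panel(synthetic_panel_path()))
  expect_equal(call$type, "III")
  expect_equal(call$nearest_identity, 1)
})

test_that("residue mapping is exact on identity and simple shifts", {
  p <- random_protein(80L, seed = 5)
  id_map <- map_residues(p, p, c(1L, 40L, 80L))
  expect_equal(id_map$query_pos, c(1L, 40L, 80L))
  expect_equal(id_map$query_residue, id_map$ref_residue)

  # one residue inserted at the query front shifts every mapping by +1
  q <- paste0("M", p)
  shifted <- map_residues(q, p, c(5L, 33L, 72L))
  expect_equal(shifted$query_pos, c(6L, 34L, 73L))

  expect_error(map_residues(p, p, 81L), "out of range")
})

test_that("residue mapping is monotone and involution-consistent", {
  loc <- synthetic_crte_locus(seed = 2)
  hom <- synthetic_sc_homolog(loc$protein, seed = 2)
  fwd <- map_residues(loc$protein, hom$protein, seq(10L, 370L, by = 20L))
  ok <- !is.na(fwd$query_pos)
  expect_true(all(diff(fwd$query_pos[ok]) > 0))
  back <- map_residues(hom$protein, loc$protein, fwd$query_pos[ok])
  expect_equal(back$query_pos, fwd$ref_pos[ok])
})

test_that("bulky-site positions transfer between the synthetic homologs", {
  loc <- synthetic_crte_locus(seed = 1)
  hom <- synthetic_sc_homolog(loc$protein, seed = 1)
  rmap <- map_residues(loc$protein, hom$protein, c(107L, 108L, 139L))
  expect_equal(rmap$query_pos, c(110L, 111L, 141L))
  expect_equal(rmap$ref_residue, c("Y", "F", "H"))
  expect_equal(rmap$query_residue, c("Y", "F", "H"))
})
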