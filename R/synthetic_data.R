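#' Specification for a synthetic multi-exon gene
#'
#' Defaults mirror the structure of a compact fungal carotenogenic gene:
#' nine exons separated by short GT-AG introns, with an optional planted
#' ORF whose translation carries FARM/SARM motifs of a chosen GGPPS type.
#'
#' @param exon_count Number of exons (>= 1).
#' @param exon_len_range Inclusive range exon lengths are drawn from.
#' @param intron_len_range Inclusive range intron lengths are drawn from
#'   (minimum 25).
#' @param mutation_rate Per-base substitution rate applied to the exon
#'   copies in the genomic sequence (the cDNA stays unmutated).
#' @param motif_plant `"none"`, `"type_I"` or `"type_II_III"`: whether the
#'   concatenated exons carry a single complete ORF encoding a protein with
#'   planted CLD features of that type.
#' @param non_canonical_fraction Fraction of introns given non-GT-AG ends.
#' @param indel_rate Per-base insertion/deletion rate applied to genomic
#'   exon copies. Stress-testing knob only: with indels the ungapped exon
#'   model no longer holds and planted-structure recovery is not
#'   guaranteed.
#' @param seed Mandatory integer seed; generation is deterministic given
#'   the spec.
#' @return A list of class `gene_spec`.
#' @export
gene_spec <- function(exon_count = 9L, exon_len_range = c(80L, 180L),
                      intron_len_range = c(50L, 100L), mutation_rate = 0,
                      motif_plant = c("none", "type_I", "type_II_III"),
                      non_canonical_fraction = 0, indel_rate = 0, seed) {
  motif_plant <- match.arg(motif_plant)
  if (missing(seed)) stop("gene_spec requires an explicit seed",
                          call. = FALSE)
  stopifnot(exon_count >= 1L, intron_len_range[1L] >= 25L,
            exon_len_range[1L] >= 1L, mutation_rate >= 0,
            mutation_rate <= 0.25, non_canonical_fraction >= 0,
            non_canonical_fraction <= 1)
  structure(list(exon_count = as.integer(exon_count),
                 exon_len_range = as.integer(exon_len_range),
                 intron_len_range = as.integer(intron_len_range),
                 mutation_rate = mutation_rate, motif_plant = motif_plant,
                 non_canonical_fraction = non_canonical_fraction,
                 indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "gene_spec")
}

#' Generate a synthetic gene fixture with ground truth
#'
#' Builds a cDNA as a concatenation of random exons (optionally hosting a
#' planted single ORF with motif-bearing translation) and a genomic
#' sequence interleaving (optionally mutated) exon copies with GT-AG
#' introns. Deterministic for a fixed spec. Two identifiability guarantees
#' keep the planted truth well-defined: mutations are substitutions only,
#' and intron interiors are resampled whenever an alternative equal-score
#' canonical junction placement exists within 6 nt of the planted one.
#'
#' @param spec A [gene_spec()].
#' @return A list of class `gene_fixture`: `genomic` and `cdna`
#'   ([nuc_record()]s), optional `protein`, and `truth` (exon/intron
#'   intervals, ORF interval, planted motif positions, expected type).
#' @export
generate_gene <- function(spec) {
  stopifnot(inherits(spec, "gene_spec"))
  .with_seed(spec$seed, .generate_gene_impl(spec))
}

.generate_gene_impl <- function(spec) {
  nex <- spec$exon_count
  exon_len <- .runif_int(nex, spec$exon_len_range)
  total <- sum(exon_len)
  protein <- NULL
  truth_motifs <- NULL
  if (spec$motif_plant == "none") {
    cdna_seq <- .rand_dna(total)
    orf_iv <- NULL
  } else {
    min_total <- 3L * 151L + 12L
    if (total < min_total) {
      stop("infeasible spec: ", total, " nt of exon cannot host a planted ",
           "ORF (needs >= ", min_total, " nt); increase exon count/length",
           call. = FALSE)
    }
    utr5 <- 6L; utr3 <- total %% 3L + 6L
    prot_len <- (total - utr5 - utr3) %/% 3L - 1L
    pg <- .generate_protein_impl(spec$motif_plant, prot_len,
                                 with_met = TRUE)
    protein <- pg$protein
    truth_motifs <- pg$truth
    for (try in 1:25) {
      orf_nt <- .reverse_translate(protein$seq)
      u5 <- .rand_dna_no_atg(utr5)
      u3 <- .rand_dna_no_atg(utr3)
      cdna_seq <- paste0(u5, orf_nt, u3)
      found <- tryCatch(find_orf(nuc_record("tmp", cdna_seq)),
                        error = function(e) NULL)
      if (!is.null(found) && found$start == utr5 &&
          found$length_nt == 3L * (prot_len + 1L)) break
      if (try == 25L) stop("could not realize a unique planted ORF",
                           call. = FALSE)
    }
    orf_iv <- c(utr5, utr5 + 3L * (prot_len + 1L))
  }
  m <- nchar(cdna_seq)
  exon_len <- .relen_to_total(exon_len, m)
  csplit <- cumsum(exon_len)                 # 0-based exon ends on cDNA
  cstart <- c(0L, csplit[-nex])
  cch <- strsplit(cdna_seq, "", fixed = TRUE)[[1L]]
  exon_copy <- vapply(seq_len(nex), function(i) {
    .indel_dna(.mutate_dna(substr(cdna_seq, cstart[i] + 1L, csplit[i]),
                           spec$mutation_rate),
               spec$indel_rate)
  }, character(1L))
  copy_len <- nchar(exon_copy)
  nint <- nex - 1L
  intron_len <- if (nint) .runif_int(nint, spec$intron_len_range)
                else integer(0)
  noncanon <- if (nint) {
    stats::runif(nint) < spec$non_canonical_fraction
  } else logical(0)
  introns <- character(nint)
  for (i in seq_len(nint)) {
    introns[i] <- .plant_intron(intron_len[i], noncanon[i],
                                exon_copy, cch, cstart, csplit, i)
  }
  genomic_seq <- paste0(
    paste0(vapply(seq_len(nex), function(i) {
      paste0(exon_copy[i], if (i <= nint) introns[i] else "")
    }, character(1L)), collapse = ""))
  gstart <- integer(nex); gend <- integer(nex)
  off <- 0L
  for (i in seq_len(nex)) {
    gstart[i] <- off
    gend[i] <- off + copy_len[i]
    off <- gend[i] + if (i <= nint) intron_len[i] else 0L
  }
  truth <- list(
    exons = cbind(start = gstart, end = gend),
    introns = if (nint) cbind(start = gend[-nex], end = gstart[-1L])
              else matrix(integer(0), 0L, 2L),
    cdna_exons = cbind(start = cstart, end = csplit),
    canonical = !noncanon,
    orf = orf_iv, motifs = truth_motifs,
    expected_type = switch(spec$motif_plant, none = NULL, type_I = "I",
                           type_II_III = "II/III"),
    spec = unclass(spec))
  structure(list(
    genomic = nuc_record(sprintf("syngene_s%d_genomic", spec$seed),
                         genomic_seq),
    cdna = nuc_record(sprintf("syngene_s%d_cdna", spec$seed), cdna_seq),
    protein = protein, truth = truth),
    class = "gene_fixture")
}

# Draw one intron; resample the interior until the planted junction is the
# unique best-scoring canonical placement within +/-6 nt.
.plant_intron <- function(len, noncanon, exon_copy, cch, cstart, csplit,
                          i, p = align_params()) {
  donor <- if (noncanon) "CT" else "GT"
  acceptor <- if (noncanon) "AC" else "AG"
  for (try in 1:60) {
    intron <- paste0(donor, .rand_dna(len - 4L), acceptor)
    if (noncanon) return(intron)
    if (.junction_unambiguous(intron, exon_copy, cch, cstart, csplit, i,
                              p)) {
      return(intron)
    }
  }
  intron
}

# TRUE when no alternative split within +/-6 nt ties or beats the planted
# junction score (scored as the aligner scores junctions).
.junction_unambiguous <- function(intron, exon_copy, cch, cstart, csplit,
                                  i, p) {
  s0 <- csplit[i]                            # planted 0-based split
  left <- strsplit(exon_copy[i], "", fixed = TRUE)[[1L]]
  right <- strsplit(exon_copy[i + 1L], "", fixed = TRUE)[[1L]]
  ich <- strsplit(intron, "", fixed = TRUE)[[1L]]
  ilen <- length(ich)
  w <- 6L
  deltas <- (-w):w
  scores <- numeric(length(deltas))
  canon <- logical(length(deltas))
  for (di in seq_along(deltas)) {
    d <- deltas[di]
    # shifting the split by d moves |d| cDNA bases across the junction;
    # the genomic bases they would pair with come from the intron ends.
    sc <- 0
    okd <- TRUE
    if (d > 0) {
      for (t in seq_len(d)) {
        cbase <- cch[s0 + t]                 # cDNA base entering exon i
        gbase <- ich[t]                      # would pair with intron start
        old <- if (t <= length(right)) right[t] else NA
        sc <- sc + (if (!is.na(cbase) && cbase == gbase) p$match
                    else -p$mismatch) -
              (if (!is.na(old) && cbase == old) p$match else -p$mismatch)
      }
      dn <- paste0(ich[d + 1L], ich[min(d + 2L, ilen)])
      ac <- if (d >= 2L) paste0(right[d - 1L], right[d])
            else paste0(ich[ilen], right[1L])
    } else if (d < 0) {
      for (t in seq_len(-d)) {
        cbase <- cch[s0 - t + 1L]
        gbase <- ich[ilen - t + 1L]
        oldpos <- length(left) - t + 1L
        old <- if (oldpos >= 1L) left[oldpos] else NA
        sc <- sc + (if (!is.na(cbase) && cbase == gbase) p$match
                    else -p$mismatch) -
              (if (!is.na(old) && cbase == old) p$match else -p$mismatch)
      }
      nd <- -d
      dn <- if (nd >= 2L) paste0(left[length(left) - nd + 1L],
                                 left[length(left) - nd + 2L])
            else paste0(left[length(left)], ich[1L])
      ac <- paste0(ich[ilen - nd - 1L], ich[ilen - nd])
    } else {
      dn <- paste0(ich[1L], ich[2L])
      ac <- paste0(ich[ilen - 1L], ich[ilen])
    }
    canon[di] <- identical(dn, "GT") && identical(ac, "AG")
    scores[di] <- sc + if (canon[di]) p$canonical_bonus else 0
    if (!okd) scores[di] <- -Inf
  }
  planted <- which(deltas == 0L)
  all(scores[-planted] < scores[planted])
}

#' Generate a synthetic protein with a planted CLD of a chosen type
#'
#' Background residues are drawn from the 19 non-aspartate amino acids so
#' that the only aspartate-rich motifs are the planted ones and the motif
#' ground truth is unambiguous. The FARM-SARM distance is drawn from
#' `[90, 200]` residues.
#'
#' @param plant `"type_I"` (FARM `DDxxD`, aromatic -5, non-aromatic -4) or
#'   `"type_II_III"` (FARM `DDxxxxD`, small non-aromatic -5/-4).
#' @param length Protein length in residues (>= 150).
#' @param seed Integer seed.
#' @return A list of class `protein_fixture` with `protein`
#'   ([prot_record()]) and `truth` (0-based motif positions, forms,
#'   upstream residues, expected rule-stage outcome).
#' @export
generate_protein_with_cld <- function(plant = c("type_I", "type_II_III"),
                                      length = 350L, seed) {
  plant <- match.arg(plant)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length < 150L) stop("length must be >= 150", call. = FALSE)
  .with_seed(seed, {
    pg <- .generate_protein_impl(plant, as.integer(length),
                                 with_met = TRUE)
    pg$protein <- prot_record(sprintf("synprot_%s_s%d", plant,
                                      as.integer(seed)),
                              pg$protein$seq)
    structure(pg, class = "protein_fixture")
  })
}

# Core protein construction (uses the current RNG stream).
.generate_protein_impl <- function(plant, length, with_met = TRUE) {
  bg <- setdiff(AA_STANDARD, "D")
  nonaro_bg <- setdiff(bg, AROMATIC)
  small <- c("A", "S", "G", "T", "C")
  farm_len <- if (plant == "type_I") 5L else 7L
  f_max <- min(floor(0.6 * length) - farm_len, length - 98L)
  f0 <- sample(10:f_max, 1L)
  d_min <- max(90L, as.integer(ceiling(0.4 * length)) - f0)
  d_max <- min(200L, length - 8L - f0)
  dist <- if (d_min >= d_max) d_max else sample(d_min:d_max, 1L)
  s0 <- f0 + dist
  chars <- sample(bg, length, replace = TRUE)
  if (with_met) chars[1L] <- "M"
  xs <- function(k) sample(nonaro_bg, k, replace = TRUE)
  if (plant == "type_I") {
    farm <- c("D", "D", xs(2L), "D")
    u5 <- sample(AROMATIC, 1L)
    u4 <- sample(nonaro_bg, 1L)
  } else {
    farm <- c("D", "D", xs(4L), "D")
    u5 <- sample(small, 1L)
    u4 <- sample(small, 1L)
  }
  chars[(f0 + 1L):(f0 + farm_len)] <- farm
  chars[f0 - 4L] <- u5
  chars[f0 - 3L] <- u4
  sarm <- c("D", "D", xs(2L), "D")
  chars[(s0 + 1L):(s0 + 5L)] <- sarm
  list(protein = prot_record("synprot", paste(chars, collapse = "")),
       truth = list(farm_start = f0,
                    farm_form = if (plant == "type_I") "DDxxD"
                                else "DDxxxxD",
                    sarm_start = s0, upstream5 = u5, upstream4 = u4,
                    expected_rule = if (plant == "type_I") "I"
                                    else "II/III"))
}

#' Write a gene fixture to FASTA files plus a truth JSON sidecar
#'
#' @param fixture A [generate_gene()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(fixture, dir, prefix = "fixture") {
  stopifnot(inherits(fixture, "gene_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genomic = file.path(dir, paste0(prefix, "_genomic.fasta")),
    cdna = file.path(dir, paste0(prefix, "_cdna.fasta")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_fasta(fixture$genomic, paths[["genomic"]])
  write_fasta(fixture$cdna, paths[["cdna"]])
  truth <- fixture$truth
  truth$exons <- apply(truth$exons, 1L, identity, simplify = FALSE)
  truth$introns <- if (nrow(fixture$truth$introns)) {
    apply(fixture$truth$introns, 1L, identity, simplify = FALSE)
  } else list()
  truth$cdna_exons <- apply(fixture$truth$cdna_exons, 1L, identity,
                            simplify = FALSE)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Synthetic crtE-like locus
#'
#' A constructed stand-in for the *S. pararoseus* NGR *crtE* locus,
#' reproducing its printed structural features without being the deposited
#' sequence: a 1,134 nt cDNA that is a single complete ORF encoding a
#' 377-residue protein, a 1,722 nt genomic copy with 8 GT-AG introns
#' (9 exons), cloning-primer-derived 5' and 3' termini (so the protein
#' begins `MTEFYDNF` and ends `...NGTNDTH`), a `DDxxxxD` FARM at residue 78
#' with Ala73/Ser74 at CLD positions -5/-4, bulky Tyr110/Phe111/His141, and
#' a C-terminal SARM. Everything else (background residues, codon choice,
#' intron interiors, exon boundaries) is seeded-random. Property values
#' computed from this surrogate (e.g. molecular mass, pI) are properties of
#' the surrogate, not of the deposited protein.
#'
#' @param seed Integer seed for the free choices.
#' @return A `gene_fixture` list: `genomic`, `cdna`, `protein`, `truth`.
#' @export
synthetic_crte_locus <- function(seed = 1L) {
  .with_seed(as.integer(seed), .synthetic_crte_impl(as.integer(seed)))
}

.synthetic_crte_impl <- function(seed) {
  prot_len <- 377L
  bg <- setdiff(AA_STANDARD, "D")
  chars <- sample(bg, prot_len, replace = TRUE)
  chars[1:8] <- strsplit("MTEFYDNF", "")[[1L]]
  chars[9L] <- "L"                           # codon must start with C
  chars[370L] <- "T"                         # codon must end with CG
  chars[371:377] <- strsplit("NGTNDTH", "")[[1L]]
  chars[73:77] <- strsplit("ASVGQ", "")[[1L]] # CLD upstream; -5 A, -4 S
  chars[78:84] <- strsplit("DDIESAD", "")[[1L]]   # FARM, DDxxxxD form
  chars[110L] <- "Y"; chars[111L] <- "F"; chars[141L] <- "H"
  chars[315:319] <- strsplit("DDYLD", "")[[1L]]   # SARM
  protein <- prot_record("CrtE_synthetic", paste(chars, collapse = ""),
                         description = "synthetic crtE-like surrogate")
  codons <- .reverse_translate_codons(chars)
  codons[1:8] <- c("ATG", "ACG", "GAG", "TTC", "TAC", "GAC", "AAC", "TTT")
  codons[9L] <- "CTC"
  codons[370L] <- "ACG"
  codons[371:377] <- c("AAT", "GGT", "ACA", "AAC", "GAT", "ACT", "CAC")
  cdna_seq <- paste0(paste(codons, collapse = ""), "TGA")
  stopifnot(nchar(cdna_seq) == 1134L)
  cdna <- nuc_record("crtE_synthetic_cdna", cdna_seq,
                     description = "synthetic crtE-like cDNA (1,134 nt)")
  nex <- 9L
  intron_len <- rep(c(74L, 73L), length.out = 8L)  # sums to 588
  base_split <- as.integer(round(seq_len(nex - 1L) * 1134L / nex))
  jitter <- sample(-20:20, nex - 1L, replace = TRUE)
  csplit <- sort(base_split + jitter)
  csplit <- as.integer(pmin(pmax(csplit, seq_len(nex - 1L) * 30L),
                            1134L - rev(seq_len(nex - 1L)) * 30L))
  cstart <- c(0L, csplit)
  cend <- c(csplit, 1134L)
  cch <- strsplit(cdna_seq, "", fixed = TRUE)[[1L]]
  exon_copy <- substring(cdna_seq, cstart + 1L, cend)
  introns <- character(8L)
  for (i in 1:8) {
    introns[i] <- .plant_intron(intron_len[i], FALSE, exon_copy, cch,
                                cstart, cend, i)
  }
  genomic_seq <- paste0(paste0(exon_copy[1:8], introns, collapse = ""),
                        exon_copy[9L])
  stopifnot(nchar(genomic_seq) == 1722L)
  gstart <- cstart + c(0L, cumsum(intron_len))
  gend <- cend + c(0L, cumsum(intron_len))
  genomic <- nuc_record("crtE_synthetic_genomic", genomic_seq,
                        description = "synthetic crtE-like locus (1,722 bp)")
  truth <- list(
    exons = cbind(start = gstart, end = gend),
    introns = cbind(start = gend[-nex], end = gstart[-1L]),
    cdna_exons = cbind(start = cstart, end = cend),
    canonical = rep(TRUE, 8L),
    orf = c(0L, 1134L),
    motifs = list(farm_start = 77L, farm_form = "DDxxxxD",
                  sarm_start = 314L, upstream5 = "A", upstream4 = "S",
                  expected_rule = "II/III"),
    expected_type = "III", seed = seed)
  structure(list(genomic = genomic, cdna = cdna, protein = protein,
                 truth = truth),
            class = "gene_fixture")
}

#' Synthetic yeast-GGPPS-like homolog of the crtE surrogate
#'
#' Constructed homolog emulating the coordinate relationship between the
#' *S. cerevisiae* GGPPS and CrtE: relative to the crtE surrogate it lacks
#' three N-terminal residues and carries one extra residue between the
#' bulky Phe and His positions, so its residues 107, 108 and 139
#' (Tyr/Phe/His) correspond to 110, 111 and 141 in the surrogate. Scattered
#' substitutions (~5%, away from the anchor regions) emulate homolog
#' divergence.
#'
#' @param crte_protein The surrogate protein ([synthetic_crte_locus()]
#'   `$protein` by default).
#' @param seed Integer seed for the divergence substitutions.
#' @return A list with `protein` (the homolog) and `truth` (the planted
#'   position correspondences).
#' @export
synthetic_sc_homolog <- function(crte_protein = synthetic_crte_locus()$protein,
                                 seed = 1L) {
  .with_seed(as.integer(seed) + 7919L, {
    ch <- strsplit(crte_protein$seq, "", fixed = TRUE)[[1L]]
    sc <- c(ch[4:111], "G", ch[112:377])
    protected <- c(1:12, 100:150, 310:325)
    free <- setdiff(seq_along(sc), protected)
    nmut <- round(0.05 * length(sc))
    at <- sample(free, nmut)
    bg <- setdiff(AA_STANDARD, "D")
    sc[at] <- vapply(sc[at], function(r) sample(setdiff(bg, r), 1L),
                     character(1L))
    structure(list(
      protein = prot_record("ScGGPPS_synthetic", paste(sc, collapse = ""),
                            description = "synthetic yeast-like homolog"),
      truth = list(pairs = cbind(ref_pos = c(107L, 108L, 139L),
                                 query_pos = c(110L, 111L, 141L)),
                   residues = c("Y", "F", "H"))),
      class = "homolog_fixture")
  })
}

## ---- low-level helpers --------------------------------------------------

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

.rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rand_dna_no_atg <- function(n) {
  for (try in 1:50) {
    s <- .rand_dna(n)
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
  gsub("ATG", "ACG", s, fixed = TRUE)
}

.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

.indel_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- character(0)
  for (b in ch) {
    u <- stats::runif(1L)
    if (u < rate / 2) next                       # deletion
    out <- c(out, b)
    if (u >= rate / 2 && u < rate) {             # insertion after b
      out <- c(out, sample(c("A", "C", "G", "T"), 1L))
    }
  }
  paste(out, collapse = "")
}

.runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep.int(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

# Adjust exon lengths so they sum to `total` (spread the difference).
.relen_to_total <- function(len, total) {
  d <- total - sum(len)
  i <- 1L
  while (d != 0L) {
    step <- sign(d)
    if (len[i] + step >= 30L) { len[i] <- len[i] + step; d <- d - step }
    i <- i %% length(len) + 1L
  }
  len
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.reverse_translate_codons <- function(chars) {
  tab <- .codon_table()
  vapply(chars, function(a) {
    cods <- tab[[a]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1L), USE.NAMES = FALSE)
}

.reverse_translate <- function(aa_seq) {
  chars <- strsplit(aa_seq, "", fixed = TRUE)[[1L]]
  stops <- .codon_table()[["*"]]
  paste0(paste(.reverse_translate_codons(chars), collapse = ""),
         sample(stops, 1L))
}
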