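#' Scan a protein for the FARM and SARM aspartate-rich motifs
#'
#' Trans-prenyltransferases carry two aspartate-rich motifs that chelate the
#' substrate diphosphates via Mg2+: the first (FARM, `DDxxD` or `DDxxxxD`)
#' near the N-terminus and the second (SARM, `DDxxD`) near the C-terminus.
#' The FARM search is restricted to the N-terminal 60% of the protein and
#' the SARM search to the C-terminal 60%; the FARM reported is the first
#' pattern match with a valid downstream SARM, and the SARM reported is the
#' `DDxxD` match closest to the C-terminus whose distance to the FARM start
#' lies in `farm_sarm_dist`. When both FARM forms match at the same
#' position, the short `DDxxD` form is recorded.
#'
#' @param protein A [prot_record()] (or residue string), length >= 100.
#' @param farm_sarm_dist Allowed range (inclusive) of `SARM start - FARM
#'   start` in residues.
#' @return A list of motif hits of class `motif_hits`; each hit has `kind`
#'   (`"FARM"`/`"SARM"`), `start`/`end` (0-based half-open), `pattern` and,
#'   for FARM, `farm_form` (`"DDxxD"`/`"DDxxxxD"`). Empty list when no
#'   FARM/SARM pair satisfies the constraints.
#' @export
scan_motifs <- function(protein, farm_sarm_dist = c(80L, 250L)) {
  seq <- .prot_seq(protein)
  n <- nchar(seq)
  if (n < 100L) stop("protein shorter than 100 aa", call. = FALSE)
  farm_zone_end <- floor(0.6 * n)          # FARM start must lie before this
  sarm_zone_start <- ceiling(0.4 * n)      # SARM start must lie at/after
  farms <- .motif_matches(seq, "(?=(DD.{2}D))", "DDxxD")
  farms <- rbind(farms, .motif_matches(seq, "(?=(DD.{4}D))", "DDxxxxD"))
  sarms <- .motif_matches(seq, "(?=(DD.{2}D))", "DDxxD")
  if (!is.null(farms)) {
    farms <- farms[farms$start + nchar(farms$pattern) <= farm_zone_end, ,
                   drop = FALSE]
    # same-position ties: prefer the short form; then scan left to right
    farms <- farms[order(farms$start, nchar(farms$pattern)), , drop = FALSE]
    farms <- farms[!duplicated(farms$start), , drop = FALSE]
  }
  if (!is.null(sarms)) {
    sarms <- sarms[sarms$start >= sarm_zone_start, , drop = FALSE]
  }
  if (is.null(farms) || !nrow(farms) || is.null(sarms) || !nrow(sarms)) {
    return(structure(list(), class = "motif_hits"))
  }
  for (i in seq_len(nrow(farms))) {
    d <- sarms$start - farms$start[i]
    valid <- which(d >= farm_sarm_dist[1L] & d <= farm_sarm_dist[2L])
    if (length(valid)) {
      f <- farms[i, ]
      s <- sarms[valid[length(valid)], ]   # closest to the C-terminus
      farm <- list(kind = "FARM", start = f$start, end = f$start +
                     nchar(f$pattern), pattern = f$pattern,
                   farm_form = f$form)
      sarm <- list(kind = "SARM", start = s$start, end = s$start +
                     nchar(s$pattern), pattern = s$pattern)
      return(structure(list(farm, sarm), class = "motif_hits"))
    }
  }
  structure(list(), class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  if (!length(x)) { cat("<motif_hits> none\n"); return(invisible(x)) }
  for (h in x) {
    cat("<", h$kind, "> ", h$pattern, " at ", h$start + 1L, "-", h$end,
        if (!is.null(h$farm_form)) paste0(" (", h$farm_form, ")") else "",
        "\n", sep = "")
  }
  invisible(x)
}

# All (overlapping) matches of a lookahead regex; data.frame or NULL.
.motif_matches <- function(seq, regex, form) {
  m <- gregexpr(regex, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(NULL)
  starts <- as.integer(m) - 1L
  len <- if (form == "DDxxD") 5L else 7L
  data.frame(start = starts,
             pattern = substring(seq, starts + 1L, starts + len),
             form = form, stringsAsFactors = FALSE)
}

#' Extract the chain-length determination (CLD) region
#'
#' The CLD region is the FARM plus the five residues immediately upstream;
#' the bulk and aromaticity of the residues four and five positions
#' upstream of the FARM correlate with the product chain length of the
#' prenyltransferase and distinguish the GGPPS types.
#'
#' @param protein A [prot_record()] or residue string.
#' @param farm A FARM hit from [scan_motifs()].
#' @return An object of class `cld_region`: list with `sequence` (FARM plus
#'   5 upstream residues), `start` (0-based), `upstream5`/`upstream4` (the
#'   residues at FARM-5 and FARM-4) and `farm_form`.
#' @export
extract_cld <- function(protein, farm) {
  seq <- .prot_seq(protein)
  if (is.null(farm$start) || farm$kind != "FARM") {
    stop("'farm' must be a FARM motif hit", call. = FALSE)
  }
  if (farm$start < 5L) {
    stop("FARM too close to the N-terminus (needs 5 upstream residues)",
         call. = FALSE)
  }
  cld <- substring(seq, farm$start - 4L, farm$end)   # 1-based: start-5+1
  structure(list(sequence = cld, start = farm$start - 5L,
                 upstream5 = substring(seq, farm$start - 4L,
                                       farm$start - 4L),
                 upstream4 = substring(seq, farm$start - 3L,
                                       farm$start - 3L),
                 farm_form = farm$farm_form),
            class = "cld_region")
}

#' @export
print.cld_region <- function(x, ...) {
  cat("<cld_region> ", x$sequence, " at ", x$start + 1L, " (",
      x$farm_form, "; -5: ", x$upstream5, ", -4: ", x$upstream4, ")\n",
      sep = "")
  invisible(x)
}

AROMATIC <- c("F", "Y", "W")

#' Read a GGPPS reference panel
#'
#' A panel is a protein FASTA plus a two-column TSV (`id`, `type` with
#' values `I`, `II`, `III`) assigning each reference its GGPPS type. The
#' package ships a small synthetic panel
#' (`ggpps_panel_synthetic.fasta`/`.tsv` under `extdata`) that users should
#' replace with curated reference sequences.
#'
#' @param fasta Path to the panel FASTA.
#' @param types Path to the TSV; defaults to the FASTA path with extension
#'   `.tsv`.
#' @return A list of class `ggpps_panel`: list of records plus a named
#'   `type` vector.
#' @export
read_panel <- function(fasta, types = sub("\\.[^.]+$", ".tsv", fasta)) {
  recs <- read_fasta(fasta, alphabet = "protein")
  tab <- utils::read.delim(types, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id", "type") %in% names(tab))) {
    stop("panel types TSV needs columns 'id' and 'type'", call. = FALSE)
  }
  missing <- setdiff(names(recs), tab$id)
  if (length(missing)) {
    stop("panel records without a type assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(records = recs,
                 type = setNames(tab$type, tab$id)[names(recs)]),
            class = "ggpps_panel")
}

#' Path to the bundled synthetic GGPPS panel
#'
#' The bundled panel is *synthetic*: nine constructed stand-in sequences
#' carrying the CLD features of each GGPPS type (not database records), for
#' offline testing and demonstration. Replace it with curated reference
#' proteins for real analyses.
#'
#' @return Path to the panel FASTA (the types TSV sits beside it).
#' @export
synthetic_panel_path <- function() {
  system.file("extdata", "ggpps_panel_synthetic.fasta",
              package = "ggppschar", mustWork = TRUE)
}

#' Classify a GGPPS into type I / II / III from its CLD region
#'
#' Rule stage: type I iff the FARM is `DDxxD`, the residue five positions
#' upstream is aromatic (F/Y/W) and the residue four upstream is
#' non-aromatic; candidate type II/III iff the FARM is `DDxxxxD` and both
#' upstream residues are non-aromatic; otherwise unclassified. The type II
#' and type III CLD descriptions are identical, so the rule stage alone
#' cannot separate them; for a `{II,III}` candidate the call is
#' disambiguated by sequence homology: the panel reference with the highest
#' CLD identity lends its type.
#'
#' @param farm A FARM hit from [scan_motifs()] (may be `NULL`).
#' @param cld A [extract_cld()] region (may be `NULL`).
#' @param panel A [read_panel()] panel; required only when the rule stage
#'   yields the `{II,III}` candidate.
#' @return An object of class `type_call`: list with `type` (`"I"`, `"II"`,
#'   `"III"` or `"unclassified"`), `rule_stage`, `rule_evidence`,
#'   `nearest_reference` (id) and `nearest_identity` (CLD identity
#'   fraction) when homology was used.
#' @export
classify_type <- function(farm, cld, panel = NULL) {
  if (is.null(farm) || is.null(cld)) {
    return(structure(list(type = "unclassified", rule_stage = "none",
                          rule_evidence = "no FARM motif detected",
                          nearest_reference = NA_character_,
                          nearest_identity = NA_real_),
                     class = "type_call"))
  }
  u5 <- cld$upstream5; u4 <- cld$upstream4
  aro5 <- u5 %in% AROMATIC; aro4 <- u4 %in% AROMATIC
  if (cld$farm_form == "DDxxD" && aro5 && !aro4) {
    return(structure(list(
      type = "I", rule_stage = "I",
      rule_evidence = paste0("FARM DDxxD with aromatic -5 (", u5,
                             ") and non-aromatic -4 (", u4, ")"),
      nearest_reference = NA_character_, nearest_identity = NA_real_),
      class = "type_call"))
  }
  if (cld$farm_form == "DDxxxxD" && !aro5 && !aro4) {
    if (is.null(panel)) {
      stop("panel required: the CLD rule alone cannot separate types II ",
           "and III", call. = FALSE)
    }
    # the rule stage has already excluded type I, so homology picks among
    # type II/III references only
    ids <- names(panel$records)[panel$type %in% c("II", "III")]
    if (!length(ids)) {
      stop("panel required: no type II/III references available",
           call. = FALSE)
    }
    identity <- vapply(ids, function(id) {
      ref <- panel$records[[id]]
      hits <- tryCatch(scan_motifs(ref), error = function(e) list())
      if (!length(hits)) return(NA_real_)
      ref_cld <- extract_cld(ref, hits[[1L]])
      .cld_identity(cld$sequence, ref_cld$sequence)
    }, numeric(1))
    if (all(is.na(identity))) {
      stop("no panel reference with a detectable CLD region",
           call. = FALSE)
    }
    best <- which.max(identity)
    return(structure(list(
      type = unname(panel$type[ids[best]]), rule_stage = "II/III",
      rule_evidence = paste0("FARM DDxxxxD with non-aromatic -5 (", u5,
                             ") and -4 (", u4, "); assigned by CLD ",
                             "homology to ", ids[best]),
      nearest_reference = ids[best],
      nearest_identity = unname(identity[best])),
      class = "type_call"))
  }
  structure(list(type = "unclassified", rule_stage = "none",
                 rule_evidence = paste0(
                   "CLD pattern (", cld$farm_form, ", -5 ", u5, ", -4 ",
                   u4, ") matches no type rule"),
                 nearest_reference = NA_character_,
                 nearest_identity = NA_real_),
            class = "type_call")
}

#' @export
print.type_call <- function(x, ...) {
  cat("<type_call> GGPPS type ", x$type, "\n  ", x$rule_evidence, "\n",
      sep = "")
  invisible(x)
}

# Identity fraction between two CLD strings: positional identity when equal
# length, else identity over a global alignment.
.cld_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]]
    return(mean(ca == cb))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 1,
    type = "global")
  Biostrings::pid(pa, type = "PID1") / 100
}

#' Map annotated residue positions between homologs
#'
#' Aligns two proteins globally (Needleman-Wunsch, BLOSUM62, affine gaps,
#' open 10 / extend 1) and reports, for each requested 1-based reference
#' position, the aligned query position and the residues on both sides.
#' Positions falling opposite an alignment gap map to `NA`.
#'
#' @param query A [prot_record()] (or residue string).
#' @param reference A [prot_record()] (or residue string).
#' @param positions Integer vector of 1-based positions on `reference`.
#' @return A data.frame of class `residue_map` with columns `ref_pos`,
#'   `query_pos`, `ref_residue`, `query_residue`.
#' @export
map_residues <- function(query, reference, positions) {
  qseq <- .prot_seq(query); rseq <- .prot_seq(reference)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > nchar(rseq))) {
    stop("position out of range of the reference protein", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qseq), Biostrings::AAString(rseq),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 1,
    type = "global")
  qal <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  ral <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  qpos <- cumsum(qal != "-")
  rpos <- cumsum(ral != "-")
  out <- data.frame(ref_pos = positions, query_pos = NA_integer_,
                    ref_residue = substring(rseq, positions, positions),
                    query_residue = NA_character_)
  for (i in seq_along(positions)) {
    col <- which(rpos == positions[i] & ral != "-")[1L]
    if (!is.na(col) && qal[col] != "-") {
      out$query_pos[i] <- qpos[col]
      out$query_residue[i] <- qal[col]
    }
  }
  class(out) <- c("residue_map", "data.frame")
  out
}

#' @export
print.residue_map <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}
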