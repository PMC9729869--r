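#' Find the longest complete open reading frame
#'
#' Scans the three forward frames for ATG-initiated, stop-terminated reading
#' frames and returns the longest one (ties broken by the smallest start
#' coordinate). The interval includes the stop codon. Only the forward
#' strand is considered.
#'
#' @param cdna A [nuc_record()] (or path to a single-record FASTA).
#' @return An object of class `orf_call`: list with `start`, `end` (0-based
#'   half-open on the cDNA, stop codon included), `frame` (0/1/2),
#'   `length_nt` and `complete = TRUE`.
#' @examples
#' find_orf(nuc_record("x", "ATGTAA"))
#' @export
find_orf <- function(cdna) {
  cdna <- .as_nuc(cdna, "cdna")
  seq <- cdna$seq
  n <- nchar(seq)
  if (n < 6L) stop("sequence shorter than 6 nt cannot contain an ORF",
                   call. = FALSE)
  codons_at <- function(pos) substring(seq, pos, pos + 2L)
  best <- NULL
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    cod <- codons_at(starts)
    is_atg <- cod == "ATG"
    is_stop <- cod %in% c("TAA", "TAG", "TGA")
    stop_idx <- which(is_stop)
    for (a in which(is_atg)) {
      s <- stop_idx[stop_idx > a]
      if (!length(s)) next
      s <- s[1L]
      # skip ATGs inside an ORF already terminated by an earlier stop:
      # the longest ORF from this frame region starts at the first ATG
      len <- (s - a + 1L) * 3L
      cand <- list(start = starts[a] - 1L, end = starts[s] + 2L,
                   frame = frame, length_nt = len)
      if (is.null(best) || len > best$length_nt ||
          (len == best$length_nt && cand$start < best$start)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("no ORF: no complete ATG..stop reading frame on the forward ",
         "strand of '", cdna$id, "'", call. = FALSE)
  }
  structure(c(best, list(complete = TRUE, cdna_id = cdna$id)),
            class = "orf_call")
}

#' @export
print.orf_call <- function(x, ...) {
  cat("<orf_call> ", x$cdna_id, " [", x$start + 1L, "-", x$end,
      "] frame ", x$frame, ", ", x$length_nt, " nt (",
      x$length_nt / 3L - 1L, " aa + stop)\n", sep = "")
  invisible(x)
}

#' Translate an ORF with the standard genetic code
#'
#' The stop codon is not included in the protein. Ambiguous bases (`N`) or
#' an internal stop codon inside the ORF are errors.
#'
#' @param orf An [find_orf()] result.
#' @param cdna The [nuc_record()] the ORF was called on.
#' @param id Identifier for the protein record (default derives from the
#'   cDNA id).
#' @return A [prot_record()].
#' @export
translate_orf <- function(orf, cdna, id = NULL) {
  stopifnot(inherits(orf, "orf_call"))
  cdna <- .as_nuc(cdna, "cdna")
  nt <- substr(cdna$seq, orf$start + 1L, orf$end)
  if (nchar(nt) %% 3L != 0L) {
    stop("ORF length not divisible by 3", call. = FALSE)
  }
  if (grepl("N", nt, fixed = TRUE)) {
    stop("ambiguous base 'N' inside ORF", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  if (!endsWith(aa, "*")) stop("ORF does not end in a stop codon",
                               call. = FALSE)
  aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE)) {
    stop("internal stop codon at residue ",
         regexpr("*", aa, fixed = TRUE)[1L], call. = FALSE)
  }
  prot_record(id %||% paste0(cdna$id, "_prot"), aa,
              description = paste0("translation of ", cdna$id, " [",
                                   orf$start + 1L, "-", orf$end, "]"))
}

# Average (not monoisotopic) residue masses in Da, plus one water per chain;
# the standard values used by common proteomics property calculators.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_AVG_MASS <- 18.01524

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water (18.01524 Da). Average
#' masses (rather than monoisotopic) are used, matching standard protein
#' property calculators.
#'
#' @param protein A [prot_record()] (or plain string over the 20 standard
#'   residues).
#' @return Mass in Da (full precision; report in kDa to 2 dp).
#' @examples
#' molecular_weight(prot_record("g", "G"))  # 75.06714
#' @export
molecular_weight <- function(protein) {
  seq <- .prot_seq(protein)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sum(AA_AVG_MASS[chars]) + WATER_AVG_MASS
}

#' Bjellqvist pKa set
#'
#' The ionizable-group pKa values of the Bjellqvist model, the set behind
#' the widely used ProtParam-style pI predictors: side chains of D, E, C, Y,
#' H, K, R, a C-terminal carboxyl (residue-specific for terminal D/E) and a
#' residue-specific N-terminal amine. Pass a modified copy to
#' [isoelectric_point()] to use a different calibration.
#'
#' @return A list with elements `side` (named vector), `nterm` (named
#'   vector of residue-specific N-terminal pKa, `default` entry used
#'   otherwise) and `cterm` (likewise).
#' @export
pka_bjellqvist <- function() {
  list(
    side = c(C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0, R = 12.0,
             Y = 10.0),
    nterm = c(default = 7.5, A = 7.59, M = 7.0, S = 6.93, P = 8.36,
              T = 6.82, V = 7.44, E = 7.7),
    cterm = c(default = 3.55, D = 4.55, E = 4.75))
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminal amine, C-terminal carboxyl
#' and the side chains of D, E, C, Y (acidic) and H, K, R (basic). Strictly
#' decreasing in pH.
#'
#' @param protein A [prot_record()] or residue string.
#' @param ph pH in `[0, 14]`.
#' @param pka A pKa table as returned by [pka_bjellqvist()].
#' @return Net charge (elementary charges).
#' @export
net_charge <- function(protein, ph, pka = pka_bjellqvist()) {
  stopifnot(ph >= 0, ph <= 14)
  seq <- .prot_seq(protein)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = AA_STANDARD))
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - ph))
  nt_res <- chars[1L]
  ct_res <- chars[length(chars)]
  pk <- pka
  nterm_pk <- if (nt_res %in% names(pk$nterm)) pk$nterm[[nt_res]]
              else pk$nterm[["default"]]
  cterm_pk <- if (ct_res %in% names(pk$cterm)) pk$cterm[[ct_res]]
              else pk$cterm[["default"]]
  charge <- pos_frac(nterm_pk) + neg_frac(cterm_pk)
  for (res in c("H", "K", "R")) {
    charge <- charge + counts[[res]] * pos_frac(pk$side[[res]])
  }
  for (res in c("D", "E", "C", "Y")) {
    charge <- charge + counts[[res]] * neg_frac(pk$side[[res]])
  }
  unname(charge)
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [net_charge()] is zero by bisection on `[0, 14]`
#' to `|charge| < tol`. Since the charge is strictly decreasing in pH the
#' root is unique.
#'
#' @inheritParams net_charge
#' @param tol Charge tolerance at convergence.
#' @return pI in pH units (full precision; report to 2 dp).
#' @export
isoelectric_point <- function(protein, pka = pka_bjellqvist(),
                              tol = 1e-4) {
  seq <- .prot_seq(protein)
  lo <- 0; hi <- 14
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Protein statistics block
#'
#' Length, average molecular mass, isoelectric point and residue
#' composition, bundled the way the characterization report consumes them.
#'
#' @inheritParams net_charge
#' @return An object of class `protein_stats`.
#' @export
protein_stats <- function(protein, pka = pka_bjellqvist()) {
  seq <- .prot_seq(protein)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  structure(list(
    length = nchar(seq),
    mw_da = molecular_weight(seq),
    pi = isoelectric_point(seq, pka),
    composition = table(factor(chars, levels = AA_STANDARD))),
    class = "protein_stats")
}

#' @export
print.protein_stats <- function(x, ...) {
  cat("<protein_stats> ", x$length, " aa, ",
      formatC(x$mw_da / 1000, format = "f", digits = 2), " kDa, pI ",
      formatC(x$pi, format = "f", digits = 2), "\n", sep = "")
  invisible(x)
}

# Validated residue string from a prot_record or plain string.
.prot_seq <- function(protein) {
  if (inherits(protein, "prot_record")) return(protein$seq)
  if (is.character(protein) && length(protein) == 1L) {
    return(prot_record("x", protein)$seq)
  }
  stop("expected a prot_record or a residue string", call. = FALSE)
}
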