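#' Nucleotide sequence record
#'
#' A validated nucleotide sequence. Input is case-folded to upper case and
#' `U` is mapped to `T`, so RNA-style input is tolerated; any character
#' outside `A`, `C`, `G`, `T`, `N` is rejected with an error naming the
#' record and the offending character.
#'
#' @param id Record identifier (single non-empty string).
#' @param seq Nucleotide sequence (single non-empty string).
#' @param description Optional free-text description.
#' @return An object of class `nuc_record` with fields `id`, `description`
#'   and `seq`.
#' @examples
#' nuc_record("x", "acgu")$seq  # "ACGT"
#' @export
nuc_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(gsub("[ \t\r\n]", "", seq))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (!nzchar(seq)) {
    stop("record '", id, "': empty sequence", call. = FALSE)
  }
  bad <- .first_illegal(seq, c("A", "C", "G", "T", "N"))
  if (!is.na(bad)) {
    stop("record '", id, "': illegal nucleotide character '",
         substr(seq, bad, bad), "' at position ", bad, call. = FALSE)
  }
  structure(list(id = id, description = description, seq = seq),
            class = "nuc_record")
}

#' Protein sequence record
#'
#' A validated amino-acid sequence over the 20 standard residues. Ambiguity
#' codes (`X`, `B`, `Z`) and stop marks (`*`) are rejected: downstream
#' physicochemical property computation is only defined for standard
#' residues.
#'
#' @inheritParams nuc_record
#' @return An object of class `prot_record`.
#' @export
prot_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(gsub("[ \t\r\n]", "", seq))
  if (!nzchar(seq)) {
    stop("record '", id, "': empty sequence", call. = FALSE)
  }
  bad <- .first_illegal(seq, AA_STANDARD)
  if (!is.na(bad)) {
    stop("record '", id, "': illegal amino-acid character '",
         substr(seq, bad, bad), "' at position ", bad, call. = FALSE)
  }
  structure(list(id = id, description = description, seq = seq),
            class = "prot_record")
}

#' @export
print.nuc_record <- function(x, ...) {
  cat("<nuc_record> ", x$id, "  (", nchar(x$seq), " nt)\n", sep = "")
  cat(" ", .abbrev_seq(x$seq), "\n", sep = "")
  invisible(x)
}

#' @export
print.prot_record <- function(x, ...) {
  cat("<prot_record> ", x$id, "  (", nchar(x$seq), " aa)\n", sep = "")
  cat(" ", .abbrev_seq(x$seq), "\n", sep = "")
  invisible(x)
}

# The 20 standard amino-acid one-letter codes.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Position of the first character of `seq` not in `allowed`, or NA.
.first_illegal <- function(seq, allowed) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% allowed))
  if (length(bad)) bad[1L] else NA_integer_
}

.abbrev_seq <- function(seq, n = 60L) {
  if (nchar(seq) <= n) seq else paste0(substr(seq, 1L, n), "...")
}

# Coerce a path or record to the requested record class.
.as_nuc <- function(x, what = "sequence") {
  if (inherits(x, "nuc_record")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    recs <- read_fasta(x, alphabet = "nucleotide")
    if (length(recs) != 1L) {
      stop(what, " file '", x, "' must contain exactly one record",
           call. = FALSE)
    }
    return(recs[[1L]])
  }
  stop(what, " must be a nuc_record or a path to a single-record FASTA",
       call. = FALSE)
}

.as_prot <- function(x, what = "protein") {
  if (inherits(x, "prot_record")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    recs <- read_fasta(x, alphabet = "protein")
    if (length(recs) != 1L) {
      stop(what, " file '", x, "' must contain exactly one record",
           call. = FALSE)
    }
    return(recs[[1L]])
  }
  stop(what, " must be a prot_record or a path to a single-record FASTA",
       call. = FALSE)
}
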