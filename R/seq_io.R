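#' Read a FASTA file into validated records
#'
#' Order is preserved, sequences are upper-cased and whitespace-stripped, and
#' every record is validated against the requested alphabet. Duplicate ids,
#' empty sequences, malformed headers and illegal characters are errors: a
#' file is never silently truncated.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A named list of [nuc_record()] or [prot_record()] objects, one per
#'   FASTA entry, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path, call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("malformed FASTA (", path, "): first line is not a '>' header",
         call. = FALSE)
  }
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("[ \t].*$", "", headers)
  descs <- ifelse(grepl("[ \t]", headers),
                  sub("^[^ \t]+[ \t]+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("malformed FASTA (", path, "): header with empty id", call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate record id '", dup[1L], "' in ", path, call. = FALSE)
  }
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste,
                 character(1L), collapse = "")
  # split() drops headers with no sequence lines; re-expand to catch them
  full <- setNames(character(length(ids)), as.character(seq_along(ids)))
  full[names(seqs)] <- seqs
  maker <- if (alphabet == "nucleotide") nuc_record else prot_record
  recs <- lapply(seq_along(ids), function(i) {
    if (!nzchar(full[[i]])) {
      stop("record '", ids[i], "': empty sequence", call. = FALSE)
    }
    maker(ids[i], full[[i]], descs[i])
  })
  names(recs) <- ids
  recs
}

#' Write records to a FASTA file
#'
#' @param records A single record or a list of `nuc_record`/`prot_record`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, c("nuc_record", "prot_record"))) {
    records <- list(records)
  }
  out <- unlist(lapply(records, function(r) {
    hdr <- if (nzchar(r$description)) paste0(">", r$id, " ", r$description)
           else paste0(">", r$id)
    n <- nchar(r$seq)
    starts <- seq(1L, n, by = width)
    c(hdr, substring(r$seq, starts, pmin(starts + width - 1L, n)))
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal reader for single-record GenBank flat files: returns the ORIGIN
#' sequence as a validated [nuc_record()] and, when a `CDS` feature is
#' present, its coordinates converted to the package's internal 0-based
#' half-open convention. `join(..)` locations are supported; reverse-strand
#' (`complement`) CDS features are rejected since only the forward strand is
#' modeled.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with elements `record` (a `nuc_record`) and `cds` (an
#'   integer matrix of 0-based half-open intervals with columns
#'   `start`,`end`, or `NULL` when no CDS feature exists).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  acc_line <- c(grep("^VERSION", lines, value = TRUE),
                grep("^ACCESSION", lines, value = TRUE))
  id <- if (length(acc_line)) {
    strsplit(trimws(sub("^\\S+", "", acc_line[1L])), "\\s+")[[1L]][1L]
  } else if (length(locus)) {
    strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
  } else {
    stop("malformed GenBank file (no LOCUS line): ", path, call. = FALSE)
  }
  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) {
    stop("malformed GenBank file (missing ORIGIN block): ", path,
         call. = FALSE)
  }
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[1L]][1L]
            else length(lines) + 1L
  seq_lines <- lines[seq(origin_at[1L] + 1L, end_at - 1L)]
  seq <- gsub("[0-9 /]", "", paste(seq_lines, collapse = ""))
  cds <- .gb_cds_intervals(lines, origin_at[1L])
  list(record = nuc_record(id, seq), cds = cds)
}

# Extract the first CDS feature location (with continuation lines) as a
# 0-based half-open interval matrix, or NULL.
.gb_cds_intervals <- function(lines, origin_at) {
  feat <- grep("^\\s{5}CDS\\s+", lines)
  feat <- feat[feat < origin_at]
  if (!length(feat)) return(NULL)
  loc <- trimws(sub("^\\s{5}CDS\\s+", "", lines[feat[1L]]))
  i <- feat[1L] + 1L
  # location may continue over lines until a /qualifier or new feature key
  while (i < origin_at && grepl("^\\s{6,}", lines[i]) &&
         !grepl("^\\s*/", trimws(lines[i], "left"))) {
    nxt <- trimws(lines[i])
    if (grepl("^/", nxt) || grepl("^[A-Za-z_'-]+\\s+(complement|join|[0-9<])", lines[i])) break
    loc <- paste0(loc, nxt)
    i <- i + 1L
  }
  if (grepl("complement", loc, fixed = TRUE)) {
    stop("reverse-strand CDS features are not supported", call. = FALSE)
  }
  loc <- gsub("join\\(|order\\(|\\)|<|>", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  ivs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1L]]
    if (length(m) != 3L) {
      if (grepl("^[0-9]+$", p)) return(c(as.integer(p) - 1L, as.integer(p)))
      stop("cannot parse CDS location: ", p, call. = FALSE)
    }
    c(as.integer(m[2L]) - 1L, as.integer(m[3L]))
  })
  mat <- do.call(rbind, ivs)
  colnames(mat) <- c("start", "end")
  mat
}

#' Fetch a GenBank accession from NCBI to a local flat file
#'
#' Convenience helper for users with network access; every other code path
#' in the package is offline. Downloads the GenBank flat file for
#' `accession` via NCBI E-utilities.
#'
#' @param accession Accession string, e.g. `"KY652916.1"`.
#' @param dest Destination path for the flat file.
#' @param timeout Seconds before the download attempt is abandoned.
#' @return Invisibly, `dest`.
#' @export
fetch_genbank <- function(accession, dest, timeout = 30) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&rettype=gb&retmode=text&id=", utils::URLencode(accession))
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  status <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
    error = function(e) {
      stop("could not fetch ", accession, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (!identical(status, 0L) || !file.exists(dest) ||
      file.info(dest)$size < 100) {
    stop("could not fetch ", accession, call. = FALSE)
  }
  invisible(dest)
}

#' Fetch a protein accession from NCBI as FASTA
#'
#' Companion to [fetch_genbank()] for protein records (e.g. reference
#' panel members or PDB chain sequences); requires network access.
#'
#' @inheritParams fetch_genbank
#' @param db NCBI database, normally `"protein"`.
#' @return Invisibly, `dest`.
#' @export
fetch_protein_fasta <- function(accession, dest, db = "protein",
                                timeout = 30) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=", db, "&rettype=fasta&retmode=text&id=",
    utils::URLencode(accession))
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  status <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
    error = function(e) {
      stop("could not fetch ", accession, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (!identical(status, 0L) || !file.exists(dest) ||
      file.info(dest)$size < 20) {
    stop("could not fetch ", accession, call. = FALSE)
  }
  invisible(dest)
}

#' Write a gene model as GFF3
#'
#' Serializes the exon chain of a [gene_model] as GFF3 gene/exon features.
#' Internal coordinates are 0-based half-open; the GFF3 output is 1-based
#' inclusive per the standard, always on the forward strand.
#'
#' @param model A `gene_model` from [align_spliced()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_gff3_exons()] for the matching reader.
#' @export
write_gff3 <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  n <- nrow(ex)
  gene_id <- paste0(model$cdna_id, ".gene")
  gr <- GenomicRanges::GRanges(
    seqnames = model$genomic_id,
    ranges = IRanges::IRanges(
      start = c(min(ex[, 1L]) + 1L, ex[, 1L] + 1L),
      end = c(max(ex[, 2L]), ex[, 2L])),
    strand = "+")
  gr$source <- "ggppschar"
  gr$type <- c("gene", rep("exon", n))
  gr$ID <- c(gene_id, paste0(gene_id, ".exon", seq_len(n)))
  gr$Parent <- c(NA_character_, rep(gene_id, n))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read exon intervals back from a GFF3 file
#'
#' @param path Path to a GFF3 file written by [write_gff3()] (or any GFF3
#'   with `exon` features on one sequence).
#' @return Integer matrix of 0-based half-open exon intervals, ordered by
#'   start, with columns `start`,`end`.
#' @export
read_gff3_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "exon"]
  mat <- cbind(start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr))
  mat[order(mat[, 1L]), , drop = FALSE]
}
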