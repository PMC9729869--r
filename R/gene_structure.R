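#' Alignment parameters for spliced cDNA-to-genomic alignment
#'
#' Scoring follows a simple additive model over an ungapped exon chain:
#' `score = matches * match - mismatches * mismatch - introns * intron_open +
#' canonical_bonus` per GT-AG intron. Exons align without indels (the model
#' targets near-identical cDNA/genomic pairs, where divergence is
#' substitutional); all cDNA/genomic length difference is absorbed by
#' introns.
#'
#' @param match Score per matched base.
#' @param mismatch Penalty per mismatched base (positive number).
#' @param intron_open Penalty per intron opened.
#' @param canonical_bonus Bonus per intron whose donor is `GT` and acceptor
#'   `AG`.
#' @param min_intron Minimum intron length in nt. 20 is below any plausible
#'   fungal intron yet blocks spurious micro-introns.
#' @param min_identity Minimum fraction of cDNA bases matched for a mapping
#'   to be accepted.
#' @param k Anchor k-mer size for the seeding stage.
#' @param refine_window Half-width (nt) of the junction shift search in
#'   [refine_boundaries()].
#' @param dp_max_combined Combined sequence length (cDNA + genomic) up to
#'   which the exact two-state dynamic program is used instead of k-mer
#'   anchoring.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = 2, intron_open = 8,
                         canonical_bonus = 4, min_intron = 20L,
                         min_identity = 0.95, k = 12L, refine_window = 3L,
                         dp_max_combined = 2000L) {
  p <- list(match = match, mismatch = mismatch, intron_open = intron_open,
            canonical_bonus = canonical_bonus,
            min_intron = as.integer(min_intron),
            min_identity = min_identity, k = as.integer(k),
            refine_window = as.integer(refine_window),
            dp_max_combined = as.integer(dp_max_combined))
  class(p) <- "align_params"
  p
}

#' Spliced alignment of a cDNA against its genomic locus
#'
#' Infers the exon/intron structure of a gene by aligning a cDNA to the
#' genomic sequence it was transcribed from. The exon chain maximizes
#' `matches * match - mismatches * mismatch - introns * intron_open +
#' canonical_bonus` per GT-AG intron, with every intron at least
#' `min_intron` nt. Two engines sit behind the same contract: exact k-mer
#' anchoring with collinear chaining and score-optimal junction placement
#' (the default), and an exact two-state dynamic program (exon state /
#' intron state) used when the combined input length is at most
#' `dp_max_combined` or the cDNA is too short to anchor.
#'
#' @param cdna A [nuc_record()] (or path to a single-record FASTA).
#' @param genomic A [nuc_record()] (or path).
#' @param params An [align_params()] list.
#' @return An object of class `gene_model`: list with `genomic_id`,
#'   `cdna_id`, `exons` and `introns` (integer matrices of 0-based half-open
#'   genomic intervals), `cdna_exons` (the matching cDNA intervals),
#'   `identity` (fraction of cDNA bases matched), `score`, `matches`,
#'   `mismatches` and the `params` used.
#' @examples
#' g <- generate_gene(gene_spec(exon_count = 3, seed = 1))
#' m <- align_spliced(g$cdna, g$genomic)
#' m$exons
#' @export
align_spliced <- function(cdna, genomic, params = align_params()) {
  cdna <- .as_nuc(cdna, "cdna")
  genomic <- .as_nuc(genomic, "genomic")
  m <- nchar(cdna$seq); n <- nchar(genomic$seq)
  if (m > n) {
    stop("cDNA (", m, " nt) is longer than the genomic sequence (", n,
         " nt)", call. = FALSE)
  }
  use_dp <- (n + m) <= params$dp_max_combined || m < 2L * params$k
  chain <- if (use_dp) .dp_align(cdna$seq, genomic$seq, params)
           else .anchor_align(cdna$seq, genomic$seq, params)
  model <- .chain_to_model(chain, cdna, genomic, params,
                           engine = if (use_dp) "dp" else "anchor")
  if (model$identity < params$min_identity) {
    stop("no spliced mapping: identity ", signif(model$identity, 4),
         " below min_identity ", params$min_identity, call. = FALSE)
  }
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$cdna_id, " on ", x$genomic_id, "\n", sep = "")
  cat("  exons: ", nrow(x$exons), "   introns: ", nrow(x$introns),
      "   identity: ", signif(x$identity, 4),
      "   score: ", x$score, "\n", sep = "")
  invisible(x)
}

#' @method summary gene_model
#' @export
summary.gene_model <- function(object, ...) {
  ex <- object$exons
  cat("Gene model: ", object$cdna_id, " mapped to ", object$genomic_id,
      " (engine: ", object$engine, ")\n", sep = "")
  cat(sprintf("  %d exons, %d introns; identity %.4f; score %g\n",
              nrow(ex), nrow(object$introns), object$identity,
              object$score))
  for (i in seq_len(nrow(ex))) {
    cat(sprintf("  exon %d: genomic %d-%d (cDNA %d-%d)\n", i,
                ex[i, 1L] + 1L, ex[i, 2L], object$cdna_exons[i, 1L] + 1L,
                object$cdna_exons[i, 2L]))
  }
  invisible(object)
}

#' Audit splice-site dinucleotides against the GT-AG rule
#'
#' Reports, for every intron of a gene model, the first two (donor) and last
#' two (acceptor) intron bases and whether the junction is canonical
#' (donor `GT`, acceptor `AG`). Spliceosomal introns overwhelmingly obey
#' this rule, so a non-canonical junction in a near-identity alignment
#' usually flags a misplaced boundary.
#'
#' @param model A `gene_model`.
#' @param genomic The genomic [nuc_record()] the model refers to.
#' @return A data.frame of class `splice_audit` with columns `intron`,
#'   `start`, `end` (1-based inclusive), `donor`, `acceptor`, `canonical`,
#'   plus attribute `all_canonical`.
#' @export
audit_splice_sites <- function(model, genomic) {
  stopifnot(inherits(model, "gene_model"))
  genomic <- .as_nuc(genomic, "genomic")
  n <- nchar(genomic$seq)
  iv <- model$introns
  k <- nrow(iv)
  if (k > 0L) {
    if (any(iv[, 1L] < 0L) || any(iv[, 2L] > n)) {
      stop("intron interval out of genomic bounds", call. = FALSE)
    }
    if (any(iv[, 2L] - iv[, 1L] < 4L)) {
      stop("intron shorter than 4 nt cannot be audited", call. = FALSE)
    }
  }
  donor <- substring(genomic$seq, iv[, 1L] + 1L, iv[, 1L] + 2L)
  acceptor <- substring(genomic$seq, iv[, 2L] - 1L, iv[, 2L])
  canonical <- donor == "GT" & acceptor == "AG"
  out <- data.frame(intron = seq_len(k), start = iv[, 1L] + 1L,
                    end = iv[, 2L], donor = donor, acceptor = acceptor,
                    canonical = canonical)
  attr(out, "all_canonical") <- all(canonical)
  class(out) <- c("splice_audit", "data.frame")
  out
}

#' @export
print.splice_audit <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("all canonical (GT-AG):", attr(x, "all_canonical"), "\n")
  invisible(x)
}

#' Refine exon/intron boundaries toward canonical GT-AG junctions
#'
#' Junction placement is ambiguous when sequence context repeats across a
#' junction: several boundary shifts can leave the alignment score
#' unchanged. Among all shifts within `refine_window` that do not decrease
#' the score, this picks the one making the intron GT..AG; among remaining
#' ties, the leftmost donor. The returned score never decreases.
#'
#' @param model A `gene_model` from [align_spliced()].
#' @param genomic,cdna The records the model was built from.
#' @param params An [align_params()] list (uses `refine_window` and the
#'   scoring constants).
#' @return A `gene_model` with possibly shifted boundaries.
#' @export
refine_boundaries <- function(model, genomic, cdna,
                              params = model$params %||% align_params()) {
  stopifnot(inherits(model, "gene_model"))
  genomic <- .as_nuc(genomic, "genomic")
  cdna <- .as_nuc(cdna, "cdna")
  nex <- nrow(model$exons)
  if (nex < 2L) return(model)
  cch <- strsplit(cdna$seq, "", fixed = TRUE)[[1L]]
  gch <- strsplit(genomic$seq, "", fixed = TRUE)[[1L]]
  splits <- model$cdna_exons[-nex, 2L]        # current 0-based split points
  diags <- model$exons[, 1L] - model$cdna_exons[, 1L]
  w <- params$refine_window
  for (j in seq_len(nex - 1L)) {
    lo <- max(splits[j] - w, model$cdna_exons[j, 1L] + 1L,
              if (j > 1L) splits[j - 1L] + 1L else -Inf)
    hi <- min(splits[j] + w, model$cdna_exons[j + 1L, 2L] - 1L,
              if (j < nex - 1L) splits[j + 1L] - 1L else Inf)
    res <- .junction_best_split(cch, gch, diags[j], diags[j + 1L],
                                as.integer(lo), as.integer(hi), params)
    splits[j] <- res$split
  }
  .rebuild_model(model, cch, gch, diags, splits, params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- internal machinery -------------------------------------------------

# Best split point s (0-based: exon A covers cdna [.., s), exon B [s, ..))
# over s in [lo, hi], scoring the window on both diagonals plus the
# canonical bonus. Ties: canonical junction first, then leftmost donor.
.junction_best_split <- function(cch, gch, dA, dB, lo, hi, p) {
  if (lo > hi) { lo <- hi <- as.integer((lo + hi) / 2) }
  s_cand <- lo:hi
  n <- length(gch)
  # clip candidates whose genomic projections fall out of bounds
  ok <- (s_cand + dA + 2L) <= n & (s_cand + dB - 2L) >= 0L &
        (s_cand + dB) <= n & (s_cand + dA) >= 0L
  if (!any(ok)) ok[which.min(abs(s_cand - (lo + hi) / 2))] <- TRUE
  s_cand <- s_cand[ok]
  window <- lo:(hi - 1L)
  if (hi > lo) {
    ca <- cch[window + 1L]
    mA <- ca == gch[window + dA + 1L]
    mB <- ca == gch[window + dB + 1L]
    valA <- ifelse(mA, p$match, -p$mismatch)
    valB <- ifelse(mB, p$match, -p$mismatch)
    cumA <- c(0, cumsum(valA))   # cumA[t+1] = score of window[1..t] on A
    cumB <- c(0, cumsum(valB))
    totB <- cumB[length(cumB)]
    base <- cumA[s_cand - lo + 1L] + (totB - cumB[s_cand - lo + 1L])
  } else {
    base <- rep(0, length(s_cand))
  }
  donor <- paste0(gch[s_cand + dA + 1L], gch[s_cand + dA + 2L])
  acceptor <- paste0(gch[s_cand + dB - 1L], gch[s_cand + dB])
  canon <- donor == "GT" & acceptor == "AG"
  score <- base + ifelse(canon, p$canonical_bonus, 0)
  best <- max(score)
  cand <- which(score == best)
  cand_canon <- cand[canon[cand]]
  pick <- if (length(cand_canon)) cand_canon[1L] else cand[1L]
  list(split = s_cand[pick], canonical = canon[pick], score = score[pick])
}

# Rebuild a gene_model from per-exon diagonals and cdna split points,
# recomputing matches/mismatches/score exactly.
.rebuild_model <- function(model, cch, gch, diags, splits, p) {
  m <- length(cch)
  nex <- length(diags)
  cstarts <- c(model$cdna_exons[1L, 1L], splits)
  cends <- c(splits, model$cdna_exons[nex, 2L])
  exons <- cbind(start = cstarts + diags, end = cends + diags)
  cdna_exons <- cbind(start = cstarts, end = cends)
  .finish_model(model$genomic_id, model$cdna_id, exons, cdna_exons,
                cch, gch, m, p, model$engine)
}

.finish_model <- function(genomic_id, cdna_id, exons, cdna_exons, cch, gch,
                          m, p, engine) {
  storage.mode(exons) <- "integer"
  storage.mode(cdna_exons) <- "integer"
  dimnames(exons) <- list(NULL, c("start", "end"))
  dimnames(cdna_exons) <- list(NULL, c("start", "end"))
  nex <- nrow(exons)
  matches <- 0L
  for (i in seq_len(nex)) {
    idx <- seq.int(cdna_exons[i, 1L] + 1L, length.out =
                     cdna_exons[i, 2L] - cdna_exons[i, 1L])
    gidx <- seq.int(exons[i, 1L] + 1L, length.out =
                      exons[i, 2L] - exons[i, 1L])
    matches <- matches + sum(cch[idx] == gch[gidx])
  }
  aligned <- sum(cdna_exons[, 2L] - cdna_exons[, 1L])
  mismatches <- aligned - matches
  introns <- if (nex > 1L) {
    cbind(start = exons[-nex, 2L], end = exons[-1L, 1L])
  } else {
    matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  }
  canon <- 0L
  if (nrow(introns)) {
    donor <- paste0(gch[introns[, 1L] + 1L], gch[introns[, 1L] + 2L])
    acceptor <- paste0(gch[introns[, 2L] - 1L], gch[introns[, 2L]])
    canon <- sum(donor == "GT" & acceptor == "AG")
  }
  score <- matches * p$match - mismatches * p$mismatch -
    nrow(introns) * p$intron_open + canon * p$canonical_bonus
  structure(list(genomic_id = genomic_id, cdna_id = cdna_id,
                 exons = exons, introns = introns,
                 cdna_exons = cdna_exons,
                 identity = matches / m, score = score,
                 matches = matches, mismatches = mismatches,
                 params = p, engine = engine),
            class = "gene_model")
}

# chain: data.frame(cstart, cend, diag) of 0-based half-open cdna intervals
# per exon, strictly increasing in cstart and diag (non-decreasing).
.chain_to_model <- function(chain, cdna, genomic, p, engine) {
  cch <- strsplit(cdna$seq, "", fixed = TRUE)[[1L]]
  gch <- strsplit(genomic$seq, "", fixed = TRUE)[[1L]]
  exons <- cbind(start = chain$cstart + chain$diag,
                 end = chain$cend + chain$diag)
  cdna_exons <- cbind(start = chain$cstart, end = chain$cend)
  .finish_model(genomic$id, cdna$id, exons, cdna_exons, cch, gch,
                length(cch), p, engine)
}

## k-mer anchoring + collinear chaining + score-optimal junction placement.
.anchor_align <- function(cseq, gseq, p) {
  m <- nchar(cseq); n <- nchar(gseq); k <- p$k
  cch <- strsplit(cseq, "", fixed = TRUE)[[1L]]
  gch <- strsplit(gseq, "", fixed = TRUE)[[1L]]
  c_km <- substring(cseq, 1:(m - k + 1L), k:m)
  g_km <- substring(gseq, 1:(n - k + 1L), k:n)
  idx <- split(seq_len(n - k + 1L), g_km)
  idx <- idx[lengths(idx) <= 10L]             # drop low-complexity repeats
  hits <- idx[c_km]
  len <- lengths(hits)
  cpos <- rep.int(seq_along(c_km), len)       # 1-based cdna anchor starts
  gpos <- unlist(hits, use.names = FALSE)
  if (!length(gpos)) {
    stop("no spliced mapping: no exact ", k, "-mer anchors between cDNA ",
         "and genomic sequence", call. = FALSE)
  }
  diag <- gpos - cpos                         # 0-based genomic offset
  segs <- .diag_segments(cpos, diag, k, max_gap = 40L)
  chain <- .chain_segments(segs, p)
  .resolve_junctions(chain, cch, gch, m, n, p)
}

# Merge anchors on each diagonal into runs; returns data.frame
# (cstart, cend, diag) with 0-based half-open cdna intervals.
.diag_segments <- function(cpos, diag, k, max_gap) {
  o <- order(diag, cpos)
  cpos <- cpos[o]; diag <- diag[o]
  newrun <- c(TRUE, diff(diag) != 0L | diff(cpos) > max_gap)
  run <- cumsum(newrun)
  cstart <- tapply(cpos, run, min) - 1L
  cend <- tapply(cpos, run, max) + k - 1L
  d <- tapply(diag, run, function(x) x[1L])
  data.frame(cstart = as.integer(cstart), cend = as.integer(cend),
             diag = as.integer(d))
}

# Collinear chaining over segments: approximate scores (exact scoring
# happens after junction resolution on the selected chain).
.chain_segments <- function(segs, p) {
  segs <- segs[order(segs$cstart, segs$diag), , drop = FALSE]
  ns <- nrow(segs)
  len <- segs$cend - segs$cstart
  best <- len * p$match
  prev <- rep.int(0L, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(i - 1L)) {
      ddiag <- segs$diag[i] - segs$diag[j]
      if (ddiag < 0L) next
      if (ddiag > 0L && ddiag < p$min_intron) next
      if (segs$cstart[i] < segs$cend[j] - 8L) next  # heavy overlap
      gap_cost <- if (ddiag == 0L) {
        max(0L, segs$cstart[i] - segs$cend[j]) * (p$mismatch / 2)
      } else {
        p$intron_open - p$canonical_bonus / 2
      }
      cand <- best[j] + len[i] * p$match - gap_cost
      if (cand > best[i]) { best[i] <- cand; prev[i] <- j }
    }
  }
  i <- which.max(best)
  path <- integer(0)
  while (i != 0L) { path <- c(i, path); i <- prev[i] }
  out <- segs[path, , drop = FALSE]
  # merge consecutive same-diagonal segments (mutation-induced splits)
  keep <- c(TRUE, diff(out$diag) != 0L)
  grp <- cumsum(keep)
  data.frame(cstart = as.integer(tapply(out$cstart, grp, min)),
             cend = as.integer(tapply(out$cend, grp, max)),
             diag = as.integer(tapply(out$diag, grp, function(x) x[1L])))
}

# Extend the chain to the cDNA ends and place each junction at the
# score-optimal split (canonical preferred, then leftmost donor).
.resolve_junctions <- function(chain, cch, gch, m, n, p) {
  nex <- nrow(chain)
  # extend outer exons along their diagonals, clipped to genomic bounds
  chain$cstart[1L] <- max(0L, -chain$diag[1L])
  chain$cend[nex] <- min(m, n - chain$diag[nex])
  if (nex == 1L) {
    return(data.frame(cstart = chain$cstart, cend = chain$cend,
                      diag = chain$diag))
  }
  splits <- integer(nex - 1L)
  for (j in seq_len(nex - 1L)) {
    lo <- max(chain$cend[j] - 6L, chain$cstart[j] + 1L)
    hi <- min(chain$cstart[j + 1L] + 6L, chain$cend[j + 1L] - 1L)
    res <- .junction_best_split(cch, gch, chain$diag[j], chain$diag[j + 1L],
                                as.integer(lo), as.integer(hi), p)
    splits[j] <- res$split
  }
  cstart <- c(chain$cstart[1L], splits)
  cend <- c(splits, chain$cend[nex])
  ok <- cend > cstart
  data.frame(cstart = cstart[ok], cend = cend[ok], diag = chain$diag[ok])
}

## Exact two-state dynamic program (exon / intron states). Used for small
## inputs and as the fallback when the cDNA is too short to anchor.
.dp_align <- function(cseq, gseq, p) {
  m <- nchar(cseq); n <- nchar(gseq)
  cch <- strsplit(cseq, "", fixed = TRUE)[[1L]]
  gch <- strsplit(gseq, "", fixed = TRUE)[[1L]]
  NEG <- -1e15
  L <- p$min_intron
  # donor_gt[a]: intron starting at 1-based genomic a begins "GT"
  donor_gt <- c(gch[-n] == "G" & gch[-1L] == "T", FALSE)
  acc_ag <- c(FALSE, gch[-n] == "A" & gch[-1L] == "G")  # acc_ag[i]: g[i-1..i]=="AG"
  E <- matrix(NEG, n + 1L, m + 1L); E[, 1L] <- 0
  Ig <- matrix(NEG, n + 1L, m + 1L)
  Io <- matrix(NEG, n + 1L, m + 1L)
  pE <- matrix(0L, n + 1L, m + 1L)
  pIg <- matrix(0L, n + 1L, m + 1L)
  pIo <- matrix(0L, n + 1L, m + 1L)
  jj <- 2L:(m + 1L)
  for (i in seq_len(n)) {
    sv <- ifelse(gch[i] == cch, p$match, -p$mismatch)   # length m
    # exon: diagonal moves from E / close from intron states
    fromE <- E[i, jj - 1L]
    bonus <- if (i >= 3L && acc_ag[i - 1L]) p$canonical_bonus else 0
    fromIg <- Ig[i, jj - 1L] + bonus
    fromIo <- Io[i, jj - 1L]
    bestprev <- pmax(fromE, fromIg, fromIo)
    E[i + 1L, jj] <- bestprev + sv
    pE[i + 1L, jj] <- ifelse(fromE >= bestprev - 1e-9, 1L,
                             ifelse(fromIg >= bestprev - 1e-9, 2L, 3L))
    # intron states: extend, or open spanning [i-L+1 .. i]
    if (i >= L + 1L) {
      a <- i - L + 1L                       # 1-based intron start
      opened <- E[a, jj] - p$intron_open    # exon ended at genomic a-1
      if (donor_gt[a]) {
        ext <- Ig[i, jj]
        Ig[i + 1L, jj] <- pmax(ext, opened)
        pIg[i + 1L, jj] <- ifelse(ext >= opened, 1L, 2L)
        Io[i + 1L, jj] <- Io[i, jj]
        pIo[i + 1L, jj] <- 1L
      } else {
        ext <- Io[i, jj]
        Io[i + 1L, jj] <- pmax(ext, opened)
        pIo[i + 1L, jj] <- ifelse(ext >= opened, 1L, 2L)
        Ig[i + 1L, jj] <- Ig[i, jj]
        pIg[i + 1L, jj] <- 1L
      }
    } else {
      Ig[i + 1L, jj] <- Ig[i, jj]; pIg[i + 1L, jj] <- 1L
      Io[i + 1L, jj] <- Io[i, jj]; pIo[i + 1L, jj] <- 1L
    }
  }
  final <- E[, m + 1L]
  i <- which.max(final)                     # row index = genomic pos + 1
  if (final[i] <= NEG / 2) {
    stop("no spliced mapping: dynamic program found no exon chain",
         call. = FALSE)
  }
  .dp_traceback(i - 1L, m, E, Ig, Io, pE, pIg, pIo, L, p)
}

# Walk pointers back from E[i, m]; returns the chain data.frame.
.dp_traceback <- function(i, j, E, Ig, Io, pE, pIg, pIo, L, p) {
  matched_g <- integer(0)
  matched_c <- integer(0)
  state <- "E"
  while (j > 0L) {
    if (state == "E") {
      ptr <- pE[i + 1L, j + 1L]
      matched_g <- c(matched_g, i)
      matched_c <- c(matched_c, j)
      if (ptr == 1L) { i <- i - 1L; j <- j - 1L }
      else if (ptr == 2L) { state <- "Ig"; i <- i - 1L; j <- j - 1L }
      else { state <- "Io"; i <- i - 1L; j <- j - 1L }
    } else {
      ptr <- if (state == "Ig") pIg[i + 1L, j + 1L] else pIo[i + 1L, j + 1L]
      if (ptr == 1L) {
        i <- i - 1L
      } else {
        i <- i - L                           # jump to exon end before intron
        state <- "E"
      }
    }
  }
  ord <- order(matched_c)
  mg <- matched_g[ord]; mc <- matched_c[ord]
  diag <- mg - mc
  newrun <- c(TRUE, diff(diag) != 0L)
  grp <- cumsum(newrun)
  data.frame(cstart = as.integer(tapply(mc, grp, min) - 1L),
             cend = as.integer(tapply(mc, grp, max)),
             diag = as.integer(tapply(diag, grp, function(x) x[1L])))
}
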