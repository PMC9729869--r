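# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (enumeration / grid search) and share no code with the
# package's optimized paths.

# All complete ATG..stop ORFs in all three forward frames by direct scan;
# returns the longest (ties: smallest start) as c(start, end) 0-based
# half-open, or NULL.
oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (i in seq_len(max(n - 5L, 0L))) {
    if (substr(seq, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substr(seq, j, j + 2L)
      if (cod %in% stops) {
        len <- j + 2L - i + 1L
        if (is.null(best) || len > best[3L]) best <- c(i - 1L, j + 2L, len)
        break
      }
      j <- j + 3L
    }
  }
  if (is.null(best)) NULL else best[1:2]
}

# pI by dense grid search: pH value minimizing |net charge| on a 1e-4 grid.
oracle_grid_pi <- function(seq, step = 1e-4) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pka <- ggppschar::pka_bjellqvist()
  ph <- seq(0, 14, by = step)
  nt <- chars[1L]; ct <- chars[length(chars)]
  nterm_pk <- if (nt %in% names(pka$nterm)) pka$nterm[[nt]]
              else pka$nterm[["default"]]
  cterm_pk <- if (ct %in% names(pka$cterm)) pka$cterm[[ct]]
              else pka$cterm[["default"]]
  q <- 1 / (1 + 10^(ph - nterm_pk)) - 1 / (1 + 10^(cterm_pk - ph))
  for (r in c("H", "K", "R")) {
    k <- sum(chars == r)
    if (k) q <- q + k / (1 + 10^(ph - pka$side[[r]]))
  }
  for (r in c("D", "E", "C", "Y")) {
    k <- sum(chars == r)
    if (k) q <- q - k / (1 + 10^(pka$side[[r]] - ph))
  }
  ph[which.min(abs(q))]
}

# Exhaustive best spliced-alignment score for <= `max_introns` introns:
# every exon chain (offsets, split points, intron lengths) is scored with
# the same additive model the aligner optimizes.
oracle_best_score <- function(cseq, gseq, p = ggppschar::align_params(),
                              max_introns = 2L) {
  m <- nchar(cseq); n <- nchar(gseq)
  cch <- strsplit(cseq, "", fixed = TRUE)[[1L]]
  gch <- strsplit(gseq, "", fixed = TRUE)[[1L]]
  dmax <- n - m
  # cum[d + 1, i + 1] = matches of cdna[1..i] on diagonal d
  cum <- matrix(0L, dmax + 1L, m + 1L)
  for (d in 0:dmax) {
    cum[d + 1L, -1L] <- cumsum(cch == gch[(1:m) + d])
  }
  w <- p$match + p$mismatch
  # bonus_vec(d1, d2)[s]: canonical bonus of intron [s + d1, s + d2)
  bonus_vec <- function(d1, d2, s) {
    don <- gch[s + d1 + 1L] == "G" & gch[s + d1 + 2L] == "T"
    acc <- gch[s + d2 - 1L] == "A" & gch[s + d2] == "G"
    ifelse(don & acc, p$canonical_bonus, 0)
  }
  best <- -Inf
  for (d in 0:dmax) {
    best <- max(best, w * cum[d + 1L, m + 1L] - p$mismatch * m)
  }
  s_all <- 1:(m - 1L)
  if (max_introns >= 1L) {
    for (d1 in 0:dmax) for (d2 in d1:dmax) {
      if (d2 - d1 < p$min_intron) next
      sc <- w * (cum[d1 + 1L, s_all + 1L] - cum[d2 + 1L, s_all + 1L]) +
        bonus_vec(d1, d2, s_all) + w * cum[d2 + 1L, m + 1L] -
        p$mismatch * m - p$intron_open
      best <- max(best, sc)
    }
  }
  if (max_introns >= 2L && m >= 3L) {
    for (d1 in 0:dmax) for (d2 in d1:dmax) {
      if (d2 - d1 < p$min_intron) next
      A <- w * (cum[d1 + 1L, s_all + 1L] - cum[d2 + 1L, s_all + 1L]) +
        bonus_vec(d1, d2, s_all)
      Amax <- cummax(A)
      for (d3 in d2:dmax) {
        if (d3 - d2 < p$min_intron) next
        B <- w * (cum[d2 + 1L, s_all + 1L] - cum[d3 + 1L, s_all + 1L]) +
          bonus_vec(d2, d3, s_all)
        tot <- Amax[s_all[-(m - 1L)]] + B[-1L] +
          w * cum[d3 + 1L, m + 1L] - p$mismatch * m - 2 * p$intron_open
        best <- max(best, tot)
      }
    }
  }
  best
}

# Brute-force FARM/SARM scan: every DDxxD / DDxxxxD occurrence by direct
# substring checks, then the selection policy applied literally.
oracle_scan <- function(seq, dist = c(80L, 250L)) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  is_m <- function(i, len) {              # 0-based start, pattern length
    idx <- i + 1L
    if (i + len > n) return(FALSE)
    ch[idx] == "D" && ch[idx + 1L] == "D" && ch[idx + len - 1L] == "D"
  }
  farms <- list()
  for (i in 0:(n - 1L)) {
    for (len in c(5L, 7L)) {
      if (is_m(i, len) && i + len <= floor(0.6 * n)) {
        farms[[length(farms) + 1L]] <- c(i, len)
        break                             # short form preferred at a tie
      }
    }
  }
  sarms <- Filter(function(x) !is.null(x), lapply(0:(n - 1L), function(i) {
    if (is_m(i, 5L) && i >= ceiling(0.4 * n)) i else NULL
  }))
  for (f in farms) {
    ok <- Filter(function(s) s - f[1L] >= dist[1L] && s - f[1L] <= dist[2L],
                 sarms)
    if (length(ok)) {
      return(list(farm_start = f[1L],
                  farm_form = if (f[2L] == 5L) "DDxxD" else "DDxxxxD",
                  sarm_start = ok[[length(ok)]]))
    }
  }
  NULL
}

# Random test protein (uniform over the 20 residues).
random_protein <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}

random_dna <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Minimal hand-built gene model for serialization tests.
make_model <- function(exons, genomic_id = "g", cdna_id = "c") {
  exons <- matrix(as.integer(exons), ncol = 2L, byrow = TRUE)
  nex <- nrow(exons)
  introns <- if (nex > 1L) cbind(exons[-nex, 2L], exons[-1L, 1L])
             else matrix(integer(0), 0L, 2L)
  len <- sum(exons[, 2L] - exons[, 1L])
  cends <- cumsum(exons[, 2L] - exons[, 1L])
  structure(list(genomic_id = genomic_id, cdna_id = cdna_id,
                 exons = exons, introns = introns,
                 cdna_exons = cbind(c(0L, cends[-nex]), cends),
                 identity = 1, score = len, matches = len, mismatches = 0L,
                 params = ggppschar::align_params(), engine = "manual"),
            class = "gene_model")
}

# Attempt to obtain a GenBank flat file for an accession: a copy placed by
# the user under extdata wins; otherwise a short network fetch is tried.
obtain_accession <- function(accession) {
  local <- system.file("extdata", paste0(accession, ".gb"),
                       package = "ggppschar")
  if (nzchar(local)) return(local)
  dest <- file.path(tempdir(), paste0(accession, ".gb"))
  if (file.exists(dest)) return(dest)
  tryCatch(ggppschar::fetch_genbank(accession, dest, timeout = 5),
           error = function(e) NULL)
}

# Same, for protein accessions (FASTA); returns a prot_record or NULL.
obtain_protein <- function(accession) {
  local <- system.file("extdata", paste0(accession, ".fasta"),
                       package = "ggppschar")
  dest <- if (nzchar(local)) local
          else file.path(tempdir(), paste0(accession, ".fasta"))
  if (!file.exists(dest)) {
    got <- tryCatch(ggppschar::fetch_protein_fasta(accession, dest,
                                                   timeout = 5),
                    error = function(e) NULL)
    if (is.null(got)) return(NULL)
  }
  ggppschar::read_fasta(dest, "protein")[[1L]]
}
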