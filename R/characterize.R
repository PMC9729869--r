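#' Run the full gene/protein characterization workflow
#'
#' Orchestrates the pipeline the package exists for: ORF finding,
#' translation, physicochemical properties, FARM/SARM/CLD motif typing,
#' and — when the corresponding inputs are given — spliced alignment of the
#' cDNA against its genomic locus with a GT-AG splice audit, and residue
#' mapping against a reference homolog. All positions in the report are
#' 1-based inclusive, matching the residue numbering conventions of the
#' literature.
#'
#' @param cdna A [nuc_record()] or path to a single-record FASTA (required).
#' @param genomic Optional genomic [nuc_record()] or path; when absent the
#'   gene block is omitted.
#' @param panel Optional [read_panel()] object or path to a panel FASTA
#'   (with sidecar `.tsv`); defaults to the bundled synthetic panel when a
#'   type call needs homology disambiguation.
#' @param reference Optional [prot_record()] or FASTA path of a reference
#'   homolog for residue mapping.
#' @param positions Integer vector of 1-based reference positions to map
#'   (required with `reference`).
#' @param config Optional path to a YAML config file or a named list;
#'   recognized keys: `align` (arguments to [align_params()]), `pka`
#'   (overrides for [pka_bjellqvist()] side-chain values),
#'   `farm_sarm_dist`.
#' @param keep_partial If `TRUE`, a stage failure yields a partial report
#'   with a `failed_stage` field instead of an error.
#' @return An object of class `ggpps_report` (nested list; see
#'   [write_report()] and the JSON schema shipped under
#'   `inst/schema/report-schema.json`).
#' @examples
#' loc <- synthetic_crte_locus(seed = 1)
#' rep <- characterize(loc$cdna, genomic = loc$genomic)
#' rep$protein$length_aa
#' @export
characterize <- function(cdna, genomic = NULL, panel = NULL,
                         reference = NULL, positions = NULL,
                         config = NULL, keep_partial = FALSE) {
  cfg <- load_config(config)
  params <- do.call(align_params, cfg$align %||% list())
  pka <- .merge_pka(cfg$pka)
  dist <- cfg$farm_sarm_dist %||% c(80L, 250L)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  report <- list(tool = "ggppschar", version = as.character(
    utils::packageVersion("ggppschar")))
  stage <- "inputs"
  run <- function(name, expr) {
    stage <<- name
    expr
  }
  result <- tryCatch({
    cdna <- .as_nuc(cdna, "cdna")
    report$inputs <- list(cdna_id = cdna$id, cdna_length = nchar(cdna$seq))
    if (!is.null(genomic)) {
      genomic <- .as_nuc(genomic, "genomic")
      report$inputs$genomic_id <- genomic$id
      report$inputs$genomic_length <- nchar(genomic$seq)
    }
    orf <- run("find_orf", find_orf(cdna))
    protein <- run("translate", translate_orf(orf, cdna))
    stats <- run("protein_props", protein_stats(protein, pka))
    report$protein <- list(
      length_aa = stats$length,
      mw_kda = round(stats$mw_da / 1000, 2),
      pi = round(stats$pi, 2),
      orf_interval_1based = c(orf$start + 1L, orf$end),
      orf_length_nt = orf$length_nt)
    note("ORF: longest complete forward-strand ORF; stop codon excluded ",
         "from the protein")
    hits <- run("scan_motifs", scan_motifs(protein, farm_sarm_dist = dist))
    if (length(hits)) {
      farm <- hits[[1L]]; sarm <- hits[[2L]]
      cld <- run("extract_cld", extract_cld(protein, farm))
      pan <- NULL
      if (farm$farm_form == "DDxxxxD") {
        pan <- run("read_panel", .resolve_panel(panel))
        if (is.null(panel)) {
          note("type II/III disambiguation used the bundled synthetic ",
               "panel; replace it with curated references for real calls")
        }
      }
      call <- run("classify_type", classify_type(farm, cld, pan))
      report$motif <- list(
        farm = list(form = farm$farm_form, start_1based = farm$start + 1L,
                    pattern = farm$pattern),
        sarm = list(start_1based = sarm$start + 1L,
                    pattern = sarm$pattern),
        cld = cld$sequence, upstream5 = cld$upstream5,
        upstream4 = cld$upstream4,
        conserved_domains_I_III_IV = "not assessed",
        type_call = call$type, rule_evidence = call$rule_evidence,
        nearest_reference = call$nearest_reference,
        nearest_identity = call$nearest_identity)
    } else {
      report$motif <- list(type_call = "unclassified",
                           rule_evidence = "no FARM/SARM pair detected",
                           conserved_domains_I_III_IV = "not assessed")
    }
    if (!is.null(genomic)) {
      model <- run("align_spliced", align_spliced(cdna, genomic, params))
      model <- run("refine_boundaries",
                   refine_boundaries(model, genomic, cdna, params))
      audit <- run("audit_splice_sites", audit_splice_sites(model, genomic))
      report$gene <- list(
        exon_count = nrow(model$exons),
        intron_count = nrow(model$introns),
        identity = model$identity,
        score = model$score,
        all_canonical = attr(audit, "all_canonical"),
        exons_1based = .iv_1based(model$exons),
        per_intron = lapply(seq_len(nrow(audit)), function(i) {
          list(start_1based = audit$start[i], end_1based = audit$end[i],
               donor = audit$donor[i], acceptor = audit$acceptor[i],
               canonical = audit$canonical[i])
        }))
      report$model <- model
    }
    if (!is.null(reference)) {
      if (is.null(positions)) {
        stop("'positions' is required with 'reference'", call. = FALSE)
      }
      reference <- .as_prot(reference, "reference")
      rmap <- run("map_residues", map_residues(protein, reference,
                                               positions))
      report$residue_map <- list(
        reference_id = reference$id,
        pairs = lapply(seq_len(nrow(rmap)), function(i) {
          list(ref_pos = rmap$ref_pos[i], query_pos = rmap$query_pos[i],
               ref_residue = rmap$ref_residue[i],
               query_residue = rmap$query_residue[i])
        }))
    }
    report$protein_record <- protein
    report
  }, error = function(e) {
    if (!keep_partial) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    }
    report$failed_stage <- stage
    report$error <- conditionMessage(e)
    report
  })
  result$config <- list(align = unclass(params),
                        pka = pka, farm_sarm_dist = dist)
  result$log <- log
  class(result) <- "ggpps_report"
  result
}

#' @export
print.ggpps_report <- function(x, ...) {
  cat("<ggpps_report> ", x$inputs$cdna_id %||% "?", "\n", sep = "")
  if (!is.null(x$failed_stage)) {
    cat("  FAILED at stage '", x$failed_stage, "': ", x$error, "\n",
        sep = "")
  }
  if (!is.null(x$gene)) {
    cat(sprintf("  gene: %d exons, %d introns, all GT-AG: %s (identity %.4f)\n",
                x$gene$exon_count, x$gene$intron_count,
                x$gene$all_canonical, x$gene$identity))
  }
  if (!is.null(x$protein)) {
    cat(sprintf("  protein: %d aa, %.2f kDa, pI %.2f (ORF %d nt)\n",
                x$protein$length_aa, x$protein$mw_kda, x$protein$pi,
                x$protein$orf_length_nt))
  }
  if (!is.null(x$motif)) {
    cat("  GGPPS type call: ", x$motif$type_call, "\n", sep = "")
    if (!is.null(x$motif$cld)) {
      cat("  CLD: ", x$motif$cld, " (-5: ", x$motif$upstream5, ", -4: ",
          x$motif$upstream4, ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a characterization report as JSON
#'
#' Serializes everything except the heavyweight internal objects (the
#' gene model and protein record, which are reconstructable from the
#' inputs). Rerunning on the same inputs and config yields byte-identical
#' JSON: the report carries no timestamps.
#'
#' @param report A [characterize()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ggpps_report"))
  out <- report[setdiff(names(report), c("model", "protein_record"))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a report against the shipped JSON schema
#'
#' Structural validation of a report JSON file (or `ggpps_report` object)
#' against `inst/schema/report-schema.json`: required top-level fields,
#' block field presence and scalar types. Returns `TRUE` invisibly or
#' raises an error listing the violations.
#'
#' @param report Path to a report JSON file or a `ggpps_report`.
#' @return Invisibly `TRUE`.
#' @export
validate_report <- function(report) {
  x <- if (inherits(report, "ggpps_report")) {
    jsonlite::fromJSON(jsonlite::toJSON(
      report[setdiff(names(report), c("model", "protein_record"))],
      auto_unbox = TRUE, digits = NA, null = "null"),
      simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(report, simplifyVector = FALSE)
  }
  schema <- jsonlite::fromJSON(system.file("schema", "report-schema.json",
                                           package = "ggppschar",
                                           mustWork = TRUE),
                               simplifyVector = FALSE)
  problems <- character(0)
  for (f in unlist(schema$required)) {
    if (is.null(x[[f]])) problems <- c(problems, paste0("missing '", f, "'"))
  }
  blocks <- schema$properties
  for (b in names(blocks)) {
    req <- unlist(blocks[[b]]$required)
    if (!is.null(x[[b]]) && length(req)) {
      for (f in req) {
        if (is.null(x[[b]][[f]])) {
          problems <- c(problems, paste0("missing '", b, ".", f, "'"))
        }
      }
    }
  }
  if (!is.null(x$protein)) {
    if (!is.numeric(x$protein$length_aa)) {
      problems <- c(problems, "'protein.length_aa' must be numeric")
    }
    if (!is.numeric(x$protein$mw_kda)) {
      problems <- c(problems, "'protein.mw_kda' must be numeric")
    }
  }
  if (length(problems)) {
    stop("report fails schema validation:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a pipeline configuration
#'
#' Configuration is YAML with optional keys `align` (passed to
#' [align_params()]), `pka` (named side-chain pKa overrides) and
#' `farm_sarm_dist`. A `NULL` input yields all defaults; a named list is
#' used as-is.
#'
#' @param config Path to a YAML file, a named list, or `NULL`.
#' @return A named list.
#' @export
load_config <- function(config = NULL) {
  if (is.null(config)) return(list())
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    return(yaml::read_yaml(config) %||% list())
  }
  if (is.list(config)) return(config)
  stop("config must be NULL, a path, or a named list", call. = FALSE)
}

.merge_pka <- function(overrides) {
  pka <- pka_bjellqvist()
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      pka$side[[nm]] <- as.numeric(overrides[[nm]])
    }
  }
  pka
}

.resolve_panel <- function(panel) {
  if (is.null(panel)) return(read_panel(synthetic_panel_path()))
  if (inherits(panel, "ggpps_panel")) return(panel)
  read_panel(panel)
}

.iv_1based <- function(mat) {
  lapply(seq_len(nrow(mat)), function(i) {
    c(mat[i, 1L] + 1L, mat[i, 2L])
  })
}
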