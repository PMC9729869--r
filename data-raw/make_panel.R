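# Builds the bundled *synthetic* GGPPS reference panel:
# nine constructed stand-in proteins (not database records), one per entry
# of a typical cross-kingdom GGPPS comparison, each carrying the CLD
# features of its type. Deterministic; rerun to regenerate
# inst/extdata/ggpps_panel_synthetic.{fasta,tsv}.

set.seed(20260923L)
AA <- c("A","C","E","F","G","H","I","K","L","M","N","P","Q","R","S","T",
        "V","W","Y")                       # background excludes D

entries <- list(
  list(id = "CrtE_typeIII_synthetic",   type = "III",
       cld = "ASVGQDDIESAD"),
  list(id = "HsGGPPS_typeIII_synthetic", type = "III",
       cld = "ASVGKDDIESAD"),            # differs from CrtE only at -1
  list(id = "RtGGPPS_typeIII_synthetic", type = "III",
       cld = "ASVGQDDIESAD"),            # identical to the CrtE CLD
  list(id = "ScGGPPS_typeIII_synthetic", type = "III",
       cld = "GSANEDDNSETD"),
  list(id = "CfGGPPS_typeIII_synthetic", type = "III",
       cld = "CSLLEDDVRGSD"),
  list(id = "AtGGPPS_typeII_synthetic",  type = "II",
       cld = "ASLVHDDLPSMD"),
  list(id = "PaGGPPS_typeII_synthetic",  type = "II",
       cld = "TSIVEDDMLEAD"),
  list(id = "GaGGPPS_typeI_synthetic",   type = "I",
       cld = "YSILQDDVMD"),
  list(id = "PhGGPPS_typeI_synthetic",   type = "I",
       cld = "FAKLEDDIQD"))

len <- 330L
farm0 <- 80L   # 0-based FARM start; CLD occupies farm0-5 .. farm0+|FARM|
sarm0 <- 240L

fasta <- character(0)
for (e in entries) {
  chars <- sample(AA, len, replace = TRUE)
  chars[1L] <- "M"
  cld <- strsplit(e$cld, "")[[1L]]
  chars[(farm0 - 4L):(farm0 - 5L + length(cld))] <- cld
  chars[(sarm0 + 1L):(sarm0 + 5L)] <-
    c("D", "D", sample(setdiff(AA, c("F","W","Y")), 2L, replace = TRUE),
      "D")
  seq <- paste(chars, collapse = "")
  fasta <- c(fasta, paste0(">", e$id, " synthetic GGPPS stand-in (type ",
                           e$type, ")"),
             substring(seq, seq(1L, len, 70L),
                       pmin(seq(1L, len, 70L) + 69L, len)))
}
writeLines(fasta, "inst/extdata/ggpps_panel_synthetic.fasta")
writeLines(c("id\ttype",
             vapply(entries, function(e) paste(e$id, e$type, sep = "\t"),
                    character(1L))),
           "inst/extdata/ggpps_panel_synthetic.tsv")
cat("panel written\n")
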