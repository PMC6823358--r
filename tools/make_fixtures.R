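# Regenerates the plain-text fixtures under inst/extdata.
# Gene symbols for repair/driver/EMT genes are real; all coordinates are a
# fixed synthetic layout (22 autosomes of 100 Mb), so no reference genome is
# needed anywhere in the pipeline.

core <- data.frame(
  gene = c("POLE", "TP53", "PTEN", "ARID1A", "PPP2R1A", "MLH1", "MSH2",
           "MSH6", "PMS2", "BRCA1", "BRCA2", "ATM", "RAD50", "BLM", "RAD51C",
           "CCNE1", "RB1", "NF1", "PIK3R1", "CTCF", "RPL22", "INPPL1",
           "KRAS", "MYC", "MECOM"),
  chrom = c("12", "17", "10", "1", "19", "3", "2",
            "2", "7", "17", "13", "11", "5", "15", "17",
            "19", "13", "17", "5", "16", "1", "11",
            "12", "8", "3"),
  stringsAsFactors = FALSE
)
n_total <- 596L
filler <- data.frame(
  gene = sprintf("CSG%03d", seq_len(n_total - nrow(core))),
  chrom = as.character(rep(1:22, length.out = n_total - nrow(core))),
  stringsAsFactors = FALSE
)
panel <- rbind(core, filler)
panel <- panel[order(as.integer(panel$chrom), panel$gene), ]
panel$start <- NA_integer_
for (ch in unique(panel$chrom)) {
  i <- which(panel$chrom == ch)
  panel$start[i] <- as.integer(2e6 + (seq_along(i) - 1L) * 3e5)
}
panel$end <- panel$start + 19999L
stopifnot(nrow(panel) == n_total, !anyDuplicated(panel$gene))
write.table(panel, "inst/extdata/panel_genes_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

regions <- do.call(rbind, lapply(1:22, function(ch) {
  data.frame(
    region_id = sprintf("chr%d%s", ch, c("p", "q")),
    chrom = as.character(ch),
    start = c(1L, 55000001L),
    end = c(45000000L, 100000000L),
    stringsAsFactors = FALSE
  )
}))
write.table(regions, "inst/extdata/subtyping_regions_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

epithelial <- c(
  "CDH1", "DSP", "EPCAM", "CLDN1", "CLDN3", "CLDN4", "CLDN7", "OCLN",
  "TJP1", "TJP3", "CRB3", "ESRP1", "ESRP2", "GRHL2", "KRT5", "KRT7",
  "KRT8", "KRT14", "KRT18", "KRT19", "MUC1", "RAB25", "ST14", "SPINT1",
  "SPINT2", "F11R", "DSG2", "DSG3", "PKP3", "JUP"
)
mesenchymal <- c(
  "VIM", "CDH2", "FN1", "ZEB1", "ZEB2", "SNAI1", "SNAI2", "TWIST1",
  "TWIST2", "FOXC1", "FOXC2", "PRRX1", "MMP2", "MMP3", "MMP9", "MMP14",
  "ACTA2", "TAGLN", "SPARC", "COL1A1", "COL1A2", "COL3A1", "COL5A1",
  "COL5A2", "COL6A3", "THBS1", "THBS2", "POSTN", "FBN1", "FAP", "PDGFRA",
  "PDGFRB", "S100A4", "ITGB1", "ITGA5", "VCAN", "LUM", "DCN", "BGN",
  "EMP3", "SERPINE1", "TNC", "WNT5A", "TGFB1", "TGFBI", "CALD1", "CNN1",
  "FSTL1", "GREM1", "INHBA", "AXL"
)
emt <- data.frame(
  gene = c(epithelial, mesenchymal),
  polarity = c(rep("epithelial", length(epithelial)),
               rep("mesenchymal", length(mesenchymal))),
  stringsAsFactors = FALSE
)
stopifnot(nrow(emt) == 81L, !anyDuplicated(emt$gene))
write.table(emt, "inst/extdata/emt_markers_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("fixtures written\n")
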