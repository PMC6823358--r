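#' Targeted gene panel (synthetic coordinates)
#'
#' The 596-locus gene panel the pipeline operates on. Gene symbols for the
#' DNA-repair and driver genes the analysis keys on are real; coordinates are
#' synthetic (a fixed arbitrary layout over 22 autosomes of 100 Mb each), so
#' no reference genome is required. Shipped as a plain-text fixture and
#' editable.
#'
#' @return Data frame: gene, chrom, start, end.
#' @export
panel_genes <- function() {
  path <- system.file("extdata", "panel_genes_synthetic.tsv",
                      package = "csgenomics", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Copy-number subtyping regions
#'
#' Chromosome-arm-level regions over which mean segmented copy number is
#' summarized for consensus clustering. A configurable stand-in for the
#' region list used in array-based endometrial-cancer subtyping.
#'
#' @return Data frame: region_id, chrom, start, end.
#' @export
subtyping_regions <- function() {
  path <- system.file("extdata", "subtyping_regions_synthetic.tsv",
                      package = "csgenomics", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' EMT marker gene panel with polarity labels
#'
#' 81 epithelial/mesenchymal marker genes used for EMT scoring. A curated
#' stand-in panel of canonical EMT markers (the scoring machinery is
#' list-agnostic); shipped as an editable fixture.
#'
#' @return Data frame: gene, polarity ("epithelial" or "mesenchymal").
#' @export
emt_marker_genes <- function() {
  path <- system.file("extdata", "emt_markers_synthetic.tsv",
                      package = "csgenomics", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Overlap length of [s1,e1] with [s2,e2], 1-based inclusive.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

#' Mean segmented log2 ratio per subtyping region
#'
#' For each sample and region, the overlap-length-weighted mean log2 ratio of
#' the copy-number segments intersecting the region; regions with no
#' overlapping segment are copy-neutral (0).
#'
#' @param profiles List of tumor profiles carrying \code{segments}.
#' @param regions Region data frame (region_id, chrom, start, end).
#' @return Numeric matrix, samples x regions, with sample ids as row names.
#' @export
region_log2r_matrix <- function(profiles, regions) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  mat <- matrix(0, nrow = length(profiles), ncol = nrow(regions),
                dimnames = list(ids, regions$region_id))
  for (i in seq_along(profiles)) {
    seg <- profiles[[i]]$segments
    if (is.null(seg) || nrow(seg) == 0L) next
    for (j in seq_len(nrow(regions))) {
      on_chrom <- seg$chrom == regions$chrom[j]
      if (!any(on_chrom)) next
      s <- seg[on_chrom, , drop = FALSE]
      w <- interval_overlap(s$start, s$end, regions$start[j], regions$end[j])
      if (sum(w) > 0) mat[i, j] <- sum(w * s$log2_ratio) / sum(w)
    }
  }
  mat
}

#' Integer copy number per gene from segments
#'
#' The integer copy number of the segment with the largest overlap with each
#' gene; genes with no overlapping segment are diploid (2).
#'
#' @param segments Segment data frame (chrom, start, end, integer_cn).
#' @param genes Gene data frame (gene, chrom, start, end); default the panel.
#' @return Named integer vector, gene -> copy number.
#' @export
gene_copy_number <- function(segments, genes = panel_genes()) {
  cn <- stats::setNames(rep(2L, nrow(genes)), genes$gene)
  if (is.null(segments) || nrow(segments) == 0L) return(cn)
  for (i in seq_len(nrow(genes))) {
    on_chrom <- segments$chrom == genes$chrom[i]
    if (!any(on_chrom)) next
    s <- segments[on_chrom, , drop = FALSE]
    w <- interval_overlap(s$start, s$end, genes$start[i], genes$end[i])
    if (any(w > 0)) cn[i] <- s$integer_cn[which.max(w)]
  }
  cn
}
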