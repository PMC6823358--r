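#' Cohort summary report with association tests
#'
#' Per-subtype burden summaries, subtype-by-clinical association tests
#' (carcinoma histology by Fisher exact test, age by Mann-Whitney U), and an
#' Oncoprint-style long-format alteration table combining driver mutations
#' and repair lesions.
#'
#' @param profiles List of (processed) tumor profiles.
#' @param subtype_calls Data frame from \code{\link{classify_cohort}}.
#' @param repair_calls Data frame from \code{\link{annotate_repair_cohort}}.
#' @return List: summary (per-subtype medians), associations (test table),
#'   oncoprint (long-format alterations).
#' @export
cohort_report <- function(profiles, subtype_calls, repair_calls) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  stopifnot(identical(ids, subtype_calls$sample_id))
  label <- subtype_calls$label

  n_snv <- vapply(profiles, function(p) sum(p$variants$variant_class == "SNV"), numeric(1))
  n_indel <- vapply(profiles, function(p) sum(p$variants$variant_class == "indel"), numeric(1))
  n_cnv <- subtype_calls$aberrant_segment_count
  summary <- do.call(rbind, lapply(c("POLE", "MSI", "CNH", "CNL"), function(st) {
    sel <- label == st
    data.frame(
      subtype = st, n = sum(sel),
      median_snv = if (any(sel)) stats::median(n_snv[sel]) else NA_real_,
      median_indel = if (any(sel)) stats::median(n_indel[sel]) else NA_real_,
      median_cnv = if (any(sel)) stats::median(n_cnv[sel]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))

  histology <- vapply(profiles, function(p) p$histology_carcinoma, character(1))
  age <- vapply(profiles, function(p) as.numeric(p$age), numeric(1))
  cnh <- label == "CNH"
  a <- sum(cnh & histology == "serous"); b <- sum(cnh & histology != "serous")
  c_ <- sum(!cnh & histology == "serous"); d <- sum(!cnh & histology != "serous")
  fisher_p <- fisher_exact_two_sided(a, b, c_, d)
  mw <- mann_whitney_u(age[cnh], age[!cnh])
  associations <- data.frame(
    test = c("CNH_vs_other_serous_histology_fisher", "CNH_vs_other_age_mann_whitney"),
    statistic = c(NA, mw$U),
    p_value = c(fisher_p, mw$p_value),
    stringsAsFactors = FALSE
  )

  onco <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    drv <- p$variants[p$variants$gene %in%
                        c("POLE", "TP53", "PTEN", "ARID1A", "PPP2R1A") &
                        p$variants$consequence != "synonymous", , drop = FALSE]
    if (nrow(drv)) {
      onco[[length(onco) + 1L]] <- data.frame(
        sample_id = p$sample_id, gene = drv$gene,
        alteration = drv$consequence, origin = "somatic",
        stringsAsFactors = FALSE
      )
    }
  }
  rc <- repair_calls[repair_calls$pathway != "none", , drop = FALSE]
  if (nrow(rc)) {
    onco[[length(onco) + 1L]] <- data.frame(
      sample_id = rc$sample_id, gene = rc$gene, alteration = rc$mechanism,
      origin = ifelse(rc$mechanism == "germline_plus_LOH", "germline", "somatic"),
      stringsAsFactors = FALSE
    )
  }
  oncoprint <- if (length(onco)) do.call(rbind, onco) else
    data.frame(sample_id = character(0), gene = character(0),
               alteration = character(0), origin = character(0))
  oncoprint <- oncoprint[order(oncoprint$sample_id, oncoprint$gene), , drop = FALSE]
  rownames(oncoprint) <- NULL

  list(summary = summary, associations = associations, oncoprint = oncoprint)
}
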