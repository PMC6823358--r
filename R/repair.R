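#' Default DNA-repair gene sets
#'
#' Mismatch-repair and homologous-recombination gene sets used by
#' \code{\link{annotate_repair_cohort}}; PTEN is carried separately because a
#' somatic PTEN mutation counts as (weak) HR evidence on its own.
#'
#' @return List with elements \code{MMR}, \code{HR}, \code{HR_methylation},
#'   \code{nonHRD_amp}, \code{nonHRD_del}.
#' @export
repair_gene_sets <- function() {
  list(
    MMR = c("MLH1", "MSH2", "MSH6", "PMS2"),
    HR = c("BRCA1", "BRCA2", "ATM", "RAD50", "BLM", "RAD51C"),
    HR_methylation = c("BRCA1", "RAD51C"),
    nonHRD_amp = "CCNE1",
    nonHRD_del = c("RB1", "NF1")
  )
}

#' Select differentially-methylated-region probes for a gene
#'
#' Probes informative for promoter hypermethylation calling: range
#' (max - min) across samples > 0.4 and median across samples < 0.1 (i.e.
#' unmethylated in most samples but strongly methylated in some).
#'
#' @param beta_matrix Numeric matrix of beta values, samples x probes.
#' @return Character vector of selected probe ids (possibly empty, with a
#'   warning: the gene is then unassessable).
#' @export
select_dmr_probes <- function(beta_matrix) {
  beta_matrix <- as.matrix(beta_matrix)
  if (nrow(beta_matrix) < 2L) stop("need at least 2 samples to select probes")
  rng <- apply(beta_matrix, 2L, function(v) max(v) - min(v))
  med <- apply(beta_matrix, 2L, stats::median)
  sel <- colnames(beta_matrix)[rng > 0.4 & med < 0.1]
  if (length(sel) == 0L) warning("no probe passes DMR selection; gene unassessable")
  sel
}

#' Promoter hypermethylation call for one sample
#'
#' Hypermethylated when the mean beta value over the selected probes is at or
#' above the 0.4 cutoff.
#'
#' @param betas Numeric vector of beta values over the selected probes.
#' @param cutoff Mean-beta cutoff (default 0.4, compared with >=).
#' @return TRUE/FALSE.
#' @export
call_hypermethylation <- function(betas, cutoff = 0.4) {
  if (length(betas) == 0L) stop("empty probe set: hypermethylation call undefined")
  mean(betas) >= cutoff
}

#' Discrete copy-number class from integer copy number
#'
#' amplification (CN >= 6), gain (CN 3-5), neutral (CN 2), loss (CN 1),
#' homozygous_deletion (CN 0).
#'
#' @param integer_cn Non-negative integer vector.
#' @return Character vector of classes.
#' @export
copy_number_class <- function(integer_cn) {
  stopifnot(all(integer_cn >= 0), all(integer_cn == round(integer_cn)))
  ifelse(integer_cn >= 6, "amplification",
         ifelse(integer_cn >= 3, "gain",
                ifelse(integer_cn == 2, "neutral",
                       ifelse(integer_cn == 1, "loss", "homozygous_deletion"))))
}

# Candidate repair mechanisms for one sample, in precedence order
# (pathway MMR > HR > nonHRD; within a pathway, promoter hypermethylation >
# germline + LOH > somatic). Returns a data frame of all candidates.
repair_candidates <- function(profile, hyper, gene_sets, require_biallelic) {
  gs <- gene_sets
  som <- profile$variants
  germ <- profile$germline
  cn <- gene_copy_number(profile$segments)
  cand <- list()
  add <- function(pathway, mechanism, gene) {
    cand[[length(cand) + 1L]] <<- data.frame(
      pathway = pathway, mechanism = mechanism, gene = gene,
      stringsAsFactors = FALSE
    )
  }

  second_hit <- function(gene, exclude_key = NULL) {
    hits <- som[som$gene == gene & som$consequence != "synonymous", , drop = FALSE]
    if (!is.null(exclude_key)) {
      hits <- hits[variant_key(hits) != exclude_key, , drop = FALSE]
    }
    nrow(hits) > 0L
  }

  # MMR: MLH1 promoter hypermethylation
  if (isTRUE(hyper["MLH1"])) add("MMR", "promoter_hypermethylation", "MLH1")
  # MMR: germline pathogenic with biallelic evidence
  if (!is.null(germ) && nrow(germ)) {
    gm <- germ[germ$gene %in% gs$MMR &
                 germ$pathogenicity %in% c("pathogenic", "likely_pathogenic"), , drop = FALSE]
    for (i in seq_len(nrow(gm))) {
      if (call_loh(gm$vaf[i]) || second_hit(gm$gene[i])) {
        add("MMR", "germline_plus_LOH", gm$gene[i])
      }
    }
  }
  # MMR: somatic truncating with biallelic evidence
  sm <- som[som$gene %in% gs$MMR & som$consequence == "truncating", , drop = FALSE]
  for (i in seq_len(nrow(sm))) {
    biallelic <- call_loh(sm$vaf[i]) || second_hit(sm$gene[i], variant_key(sm[i, ]))
    if (biallelic || !require_biallelic) add("MMR", "somatic_biallelic", sm$gene[i])
  }

  # HR: BRCA1/RAD51C promoter hypermethylation
  for (g in gs$HR_methylation) {
    if (isTRUE(hyper[g])) add("HR", "promoter_hypermethylation", g)
  }
  # HR: germline inactivation + LOH
  if (!is.null(germ) && nrow(germ)) {
    gh <- germ[germ$gene %in% gs$HR &
                 germ$pathogenicity %in% c("pathogenic", "likely_pathogenic"), , drop = FALSE]
    for (i in seq_len(nrow(gh))) {
      if (call_loh(gh$vaf[i]) || second_hit(gh$gene[i])) {
        add("HR", "germline_plus_LOH", gh$gene[i])
      }
    }
  }
  # HR: somatic PTEN mutation (nonsynonymous), weakest HR evidence
  if (any(som$gene == "PTEN" & som$consequence != "synonymous")) {
    add("HR", "somatic_PTEN", "PTEN")
  }

  # non-HRD chromosomal instability
  if (cn[gs$nonHRD_amp] >= 6L) add("nonHRD", "CCNE1_amplification", gs$nonHRD_amp)
  for (g in gs$nonHRD_del) {
    if (cn[g] == 0L) {
      add("nonHRD", paste0(g, "_homozygous_deletion"), g)
    }
  }

  if (length(cand) == 0L) return(NULL)
  out <- do.call(rbind, cand)
  mech_rank <- c(promoter_hypermethylation = 1, germline_plus_LOH = 2,
                 somatic_biallelic = 3, somatic_PTEN = 3,
                 CCNE1_amplification = 1, RB1_homozygous_deletion = 2,
                 NF1_homozygous_deletion = 2)
  path_rank <- c(MMR = 1, HR = 2, nonHRD = 3)
  out[order(path_rank[out$pathway], mech_rank[out$mechanism], out$gene), ,
      drop = FALSE]
}

#' Annotate DNA-repair deficiency mechanisms across a cohort
#'
#' Assigns each tumor exactly one repair call: MMR deficiency (MLH1 promoter
#' hypermethylation, or a germline pathogenic / somatic truncating lesion in
#' an MMR gene with biallelic evidence), HR deficiency (BRCA1/RAD51C promoter
#' hypermethylation, germline inactivation plus LOH in an HR gene, or somatic
#' PTEN mutation), non-HRD chromosomal instability (CCNE1 amplification or
#' RB1/NF1 homozygous deletion), or none. When mechanisms co-occur, precedence
#' is MMR > HR > nonHRD and, within a pathway, promoter hypermethylation >
#' germline + LOH > somatic; the losers are recorded in \code{co_occurring}.
#'
#' DMR probes are selected cohort-wide per methylation gene, then each
#' sample's mean beta over those probes is compared with the 0.4 cutoff.
#'
#' @param profiles List of tumor profiles (fields: sample_id, variants,
#'   germline, segments, beta = named list gene -> named probe beta vector).
#' @param gene_sets Gene sets, default \code{\link{repair_gene_sets}()}.
#' @param require_biallelic Require LOH or a second somatic hit for somatic
#'   MMR lesions (default TRUE).
#' @return Data frame: sample_id, pathway, mechanism, gene, co_occurring.
#' @export
annotate_repair_cohort <- function(profiles, gene_sets = repair_gene_sets(),
                                   require_biallelic = TRUE) {
  meth_genes <- c("MLH1", gene_sets$HR_methylation)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))

  # cohort-wide DMR probe selection per methylation gene
  dmr <- lapply(meth_genes, function(g) {
    betas <- lapply(profiles, function(p) p$beta[[g]])
    if (any(vapply(betas, is.null, logical(1)))) return(character(0))
    mat <- do.call(rbind, betas)
    rownames(mat) <- ids
    tryCatch(suppressWarnings(select_dmr_probes(mat)), error = function(e) character(0))
  })
  names(dmr) <- meth_genes

  rows <- lapply(profiles, function(p) {
    hyper <- vapply(meth_genes, function(g) {
      probes <- dmr[[g]]
      if (length(probes) == 0L) return(FALSE)
      call_hypermethylation(p$beta[[g]][probes])
    }, logical(1))
    cand <- repair_candidates(p, hyper, gene_sets, require_biallelic)
    if (is.null(cand)) {
      data.frame(sample_id = p$sample_id, pathway = "none",
                 mechanism = NA_character_, gene = NA_character_,
                 co_occurring = NA_character_, stringsAsFactors = FALSE)
    } else {
      top <- cand[1L, , drop = FALSE]
      others <- cand[-1L, , drop = FALSE]
      data.frame(
        sample_id = p$sample_id, pathway = top$pathway,
        mechanism = top$mechanism, gene = top$gene,
        co_occurring = if (nrow(others)) {
          paste(paste(others$pathway, others$mechanism, others$gene, sep = "/"),
                collapse = ";")
        } else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
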