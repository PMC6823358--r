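msi_markers <- c("BAT25", "BAT26", "D2S123", "D5S346", "D17S250", "BAT40")

default_pole_hotspots <- c("P286R", "V411L", "S297F", "A456P", "S459F")

#' POLE exonuclease-domain mutation call
#'
#' Scans the somatic variants of one sample for a nonsynonymous POLE mutation
#' whose codon lies inside the exonuclease (proofreading) domain, or whose
#' protein change matches a configured hotspot list. The first matching
#' variant (genomic order) is returned as evidence.
#'
#' @param variants Somatic variant data frame for one sample.
#' @param exonuclease_range Codon interval of the proofreading domain
#'   (default 268-471).
#' @param hotspot_list Protein changes accepted regardless of codon (default
#'   includes P286R and V411L).
#' @return One-row data frame of evidence, or NULL when no qualifying variant.
#' @export
call_pole <- function(variants, exonuclease_range = c(268L, 471L),
                      hotspot_list = default_pole_hotspots) {
  pole <- variants[variants$gene == "POLE" &
                     variants$consequence != "synonymous", , drop = FALSE]
  if (nrow(pole) == 0L) return(NULL)
  pole <- pole[order(pole$chrom, pole$pos), , drop = FALSE]
  for (i in seq_len(nrow(pole))) {
    pc <- sub("^p\\.", "", pole$protein_change[i])
    codon <- suppressWarnings(as.integer(sub("^[A-Za-z*]+([0-9]+).*$", "\\1", pc)))
    if (is.na(codon) && !(pc %in% hotspot_list)) {
      warning("unparseable protein change skipped: ", pole$protein_change[i])
      next
    }
    in_domain <- !is.na(codon) &&
      codon >= exonuclease_range[1L] && codon <= exonuclease_range[2L]
    if (in_domain || pc %in% hotspot_list) {
      return(pole[i, , drop = FALSE])
    }
  }
  NULL
}

#' MSI-high call from the 6-marker panel
#'
#' Microsatellite instability-high is called when 2 or more of the 6 panel
#' markers (BAT25, BAT26, D2S123, D5S346, D17S250, BAT40) deviate from the
#' matched normal.
#'
#' @param panel Named logical vector of instability flags; names must be
#'   exactly the six markers.
#' @return TRUE/FALSE.
#' @export
call_msi_high <- function(panel) {
  if (!is.logical(panel) || length(panel) != 6L ||
      !setequal(names(panel), msi_markers) || anyNA(panel)) {
    stop("MSI panel must be a named logical vector over the 6 markers: ",
         paste(msi_markers, collapse = ", "))
  }
  sum(panel) >= 2L
}

#' Consensus k-means clustering with subsampling
#'
#' k-means (Euclidean) on row-subsampled data, aggregated into a consensus
#' matrix per k: the fraction of subsampling iterations in which a pair of
#' samples was assigned to the same cluster, among iterations where both were
#' drawn. k is chosen from the relative change in the area under the
#' consensus CDF: the largest k whose area gain is still material (at least
#' \code{delta_min}), the usual practical reading of the area-change
#' criterion; final labels come from average-linkage hierarchical clustering
#' of the chosen consensus matrix.
#'
#' @param x Numeric matrix, samples x features (row names = sample ids).
#' @param k_range Candidate cluster counts (default 2:6).
#' @param reps Number of subsampling iterations (default 1000).
#' @param subsample Row subsampling ratio (default 0.8).
#' @param delta_min Minimum relative CDF-area gain for accepting a larger k
#'   (default 0.05).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @return List: \code{labels} (named integer vector for chosen k),
#'   \code{chosen_k}, \code{consensus} (list of consensus matrices per k),
#'   \code{cdf_area} and \code{delta_area} per k.
#' @export
consensus_cluster <- function(x, k_range = 2:6, reps = 1000L, subsample = 0.8,
                              delta_min = 0.05, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples to cluster")
  if (max(k_range) >= n) stop("max k must be smaller than the number of samples")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(n))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  m_sub <- max(2L, floor(subsample * n))
  consensus <- vector("list", length(k_range))
  names(consensus) <- as.character(k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    hits <- matrix(0, n, n)
    pairs <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, m_sub))
      km <- suppressWarnings(stats::kmeans(x[idx, , drop = FALSE],
                                           centers = min(k, m_sub),
                                           nstart = 1L, iter.max = 25L))
      same <- outer(km$cluster, km$cluster, "==")
      hits[idx, idx] <- hits[idx, idx] + same
      pairs[idx, idx] <- pairs[idx, idx] + 1
    }
    cm <- ifelse(pairs > 0, hits / pairs, 0)
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(x), rownames(x))
    consensus[[ki]] <- cm
  }

  cdf_area <- vapply(consensus, function(cm) {
    v <- sort(cm[lower.tri(cm)])
    if (length(v) == 0L) return(0)
    grid <- seq(0, 1, length.out = 101L)
    cdf <- stats::ecdf(v)(grid)
    sum(diff(grid) * cdf[-1L])
  }, numeric(1))
  delta_area <- cdf_area
  if (length(k_range) > 1L) {
    delta_area[-1L] <- diff(cdf_area) / pmax(cdf_area[-length(cdf_area)], .Machine$double.eps)
  }
  material <- which(delta_area >= delta_min)
  chosen_k <- if (length(material)) k_range[max(material)] else
    k_range[which.max(delta_area)]

  cm <- consensus[[as.character(chosen_k)]]
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  labels <- stats::cutree(hc, k = chosen_k)
  list(labels = labels, chosen_k = chosen_k, consensus = consensus,
       cdf_area = cdf_area, delta_area = delta_area)
}

#' Count copy-number-aberrant segments
#'
#' @param segments Segment data frame with a log2_ratio column.
#' @param threshold Absolute log2 ratio at or above which a segment counts as
#'   aberrant (default 0.3).
#' @return Integer count.
#' @export
aberrant_segment_count <- function(segments, threshold = 0.3) {
  sum(abs(segments$log2_ratio) >= threshold)
}

#' Label copy-number-high samples from consensus clusters
#'
#' A cluster is labeled CNH when its median aberrant-segment count reaches the
#' scalar burden threshold or exceeds the cohort median burden by the margin.
#' For cohorts too small to cluster meaningfully, a deterministic per-sample
#' fallback (count >= threshold) is used.
#'
#' @param labels Named integer cluster labels from \code{consensus_cluster}.
#' @param aberrant_counts Named integer vector of per-sample aberrant-segment
#'   counts (same names).
#' @param count_threshold Scalar burden threshold (default 8).
#' @param median_margin Required excess of a CNH cluster median over the
#'   cohort median (default 4, compared with >=).
#' @param min_n Below this cohort size the scalar fallback is used (default 10).
#' @return Character vector of CNH sample ids.
#' @export
assign_cnh <- function(labels, aberrant_counts, count_threshold = 8L,
                       median_margin = 4, min_n = 10L) {
  ids <- names(aberrant_counts)
  if (is.null(labels) || length(labels) < min_n) {
    return(ids[aberrant_counts >= count_threshold])
  }
  aberrant_counts <- aberrant_counts[names(labels)]
  global_median <- stats::median(aberrant_counts)
  cl_median <- tapply(aberrant_counts, labels, stats::median)
  cnh_clusters <- names(cl_median)[cl_median >= count_threshold |
                                     cl_median >= global_median + median_margin]
  names(labels)[as.character(labels) %in% cnh_clusters]
}

#' Genomic-aberration subtype decision tree over a cohort
#'
#' Ordered decision tree: a sample is POLE when it carries a somatic POLE
#' exonuclease-domain/hotspot mutation; otherwise MSI when 2+ of 6 panel
#' markers are unstable; otherwise CNH when consensus clustering of mean
#' segmented copy-number over the subtyping regions places it in a
#' high-burden cluster; the remainder is CNL.
#'
#' @param profiles List of tumor profiles (see \code{\link{generate_cohort}}
#'   for the structure: sample_id, variants, segments, msi_panel, ...).
#' @param regions Subtyping region data frame (region_id, chrom, start, end);
#'   default \code{\link{subtyping_regions}()}.
#' @param reps,k_range,subsample,seed Consensus-clustering settings (defaults
#'   1000 iterations, k in 2:6, ratio 0.8).
#' @param aberration_threshold Absolute log2 ratio defining an aberrant
#'   segment (default 0.3).
#' @param cnh_count_threshold Scalar CNH burden threshold (default 8).
#' @return Data frame: sample_id, label, pole_evidence, msi_marker_count,
#'   cn_cluster_id, aberrant_segment_count. The consensus-clustering result is
#'   attached as attribute \code{"consensus"}.
#' @export
classify_cohort <- function(profiles, regions = subtyping_regions(),
                            reps = 1000L, k_range = 2:6, subsample = 0.8,
                            seed = 1L, aberration_threshold = 0.3,
                            cnh_count_threshold = 8L) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  for (p in profiles) {
    if (is.null(p$msi_panel)) stop("missing MSI panel for sample ", p$sample_id)
  }
  pole_ev <- lapply(profiles, function(p) call_pole(p$variants))
  is_pole <- !vapply(pole_ev, is.null, logical(1))
  msi_count <- vapply(profiles, function(p) sum(p$msi_panel), integer(1))
  is_msi <- !is_pole & vapply(profiles, function(p) call_msi_high(p$msi_panel), logical(1))
  ab_count <- vapply(profiles, function(p) {
    aberrant_segment_count(p$segments, aberration_threshold)
  }, integer(1))
  names(ab_count) <- ids

  rest <- ids[!is_pole & !is_msi]
  consensus <- NULL
  cn_cluster <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  if (length(rest) > max(k_range)) {
    mat <- region_log2r_matrix(profiles[ids %in% rest], regions)
    consensus <- consensus_cluster(mat, k_range = k_range, reps = reps,
                                   subsample = subsample, seed = seed)
    cn_cluster[names(consensus$labels)] <- consensus$labels
    cnh_ids <- assign_cnh(consensus$labels, ab_count[rest],
                          count_threshold = cnh_count_threshold)
  } else {
    cnh_ids <- assign_cnh(NULL, ab_count[rest],
                          count_threshold = cnh_count_threshold)
  }

  label <- ifelse(is_pole, "POLE",
                  ifelse(is_msi, "MSI",
                         ifelse(ids %in% cnh_ids, "CNH", "CNL")))
  out <- data.frame(
    sample_id = ids,
    label = label,
    pole_evidence = vapply(pole_ev, function(e) {
      if (is.null(e)) NA_character_ else e$protein_change
    }, character(1)),
    msi_marker_count = msi_count,
    cn_cluster_id = unname(cn_cluster[ids]),
    aberrant_segment_count = unname(ab_count[ids]),
    stringsAsFactors = FALSE
  )
  attr(out, "consensus") <- consensus
  out
}

#' Driver-mutation subtype (endometrioid-like / serous-like)
#'
#' Samples with a nonsynonymous PTEN or ARID1A mutation are endometrioid-like;
#' otherwise samples with TP53 or PPP2R1A mutations are serous-like; samples
#' lacking mutations in all four genes are unclassified. When both gene pairs
#' are mutated the endometrioid rule takes precedence and the call is flagged
#' ambiguous.
#'
#' @param variants Somatic variant data frame for one sample.
#' @return List: label, triggering_genes (character), ambiguous (logical).
#' @export
driver_mutation_subtype <- function(variants) {
  ns <- variants[variants$consequence != "synonymous", , drop = FALSE]
  genes <- unique(ns$gene)
  endo <- intersect(genes, c("PTEN", "ARID1A"))
  sero <- intersect(genes, c("TP53", "PPP2R1A"))
  if (length(endo)) {
    list(label = "endometrioid_like", triggering_genes = endo,
         ambiguous = length(sero) > 0L)
  } else if (length(sero)) {
    list(label = "serous_like", triggering_genes = sero, ambiguous = FALSE)
  } else {
    list(label = "unclassified", triggering_genes = character(0), ambiguous = FALSE)
  }
}
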