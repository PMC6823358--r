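#' EMT score from the 81-gene marker panel
#'
#' The epithelial-mesenchymal transition score of each sample is its
#' projection on the first principal component of the marker-gene expression
#' matrix (log10(FPKM + 1) convention, columns centered, unscaled by
#' default). The sign of the component is arbitrary, so it is oriented with
#' the marker polarity map: if the mean loading of mesenchymal markers is
#' below that of epithelial markers the component is flipped, making
#' mesenchymal-leaning samples score high.
#'
#' @param expr Numeric matrix, samples x genes, log-transformed expression.
#' @param markers Marker data frame (gene, polarity); default the shipped
#'   81-gene panel.
#' @param scale_genes Scale genes to unit variance before PCA (default FALSE;
#'   log expression is already comparable across genes).
#' @param allow_subset Proceed with a warning when some marker genes are
#'   missing from the matrix (default FALSE: error listing them).
#' @return List: scores (named, zero mean), loadings (named), orientation_sign,
#'   variance_explained.
#' @export
emt_score <- function(expr, markers = emt_marker_genes(), scale_genes = FALSE,
                      allow_subset = FALSE) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3L) stop("need at least 3 samples for EMT scoring")
  missing <- setdiff(markers$gene, colnames(expr))
  if (length(missing)) {
    if (!allow_subset) {
      stop("marker genes missing from expression matrix: ",
           paste(missing, collapse = ", "))
    }
    warning("scoring on a marker subset; missing: ",
            paste(missing, collapse = ", "))
    markers <- markers[!(markers$gene %in% missing), , drop = FALSE]
  }
  x <- expr[, markers$gene, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = scale_genes)
  scores <- pc$x[, 1L]
  loadings <- pc$rotation[, 1L]
  mes <- markers$gene[markers$polarity == "mesenchymal"]
  epi <- markers$gene[markers$polarity == "epithelial"]
  sign_flip <- if (mean(loadings[mes]) < mean(loadings[epi])) -1 else 1
  list(
    scores = scores * sign_flip,
    loadings = loadings * sign_flip,
    orientation_sign = sign_flip,
    variance_explained = pc$sdev[1L]^2 / sum(pc$sdev^2)
  )
}

#' Association of EMT score with component content
#'
#' Spearman correlation of per-sample EMT scores with the histologically
#' estimated component fraction. With sarcoma fraction as the content axis
#' the expected correlation is positive (mesenchymal-high scoring); against
#' carcinoma content the sign inverts.
#'
#' @param scores Numeric vector of EMT scores.
#' @param content Paired numeric vector (e.g. sarcoma fraction per sample).
#' @return List: rho, p_value, n.
#' @export
score_vs_content <- function(scores, content) {
  if (length(scores) != length(content)) stop("unpaired inputs")
  if (length(scores) < 3L) stop("need at least 3 paired samples")
  rho <- spearman_rho(scores, content)
  p <- suppressWarnings(stats::cor.test(scores, content, method = "spearman",
                                        exact = FALSE)$p.value)
  list(rho = rho, p_value = p, n = length(scores))
}

#' Select most variably methylated probes
#'
#' Probes ranked by variance of beta values across samples; the top fraction
#' is retained, ties broken by probe id for determinism.
#'
#' @param beta Numeric matrix, samples x probes.
#' @param fraction Fraction of probes to keep (default 0.20).
#' @return Character vector of selected probe ids.
#' @export
top_variance_probes <- function(beta, fraction = 0.20) {
  beta <- as.matrix(beta)
  if (nrow(beta) < 2L) stop("need at least 2 samples")
  v <- apply(beta, 2L, stats::var)
  ord <- order(-v, colnames(beta))
  n_keep <- max(1L, floor(fraction * ncol(beta)))
  colnames(beta)[ord[seq_len(n_keep)]]
}

#' Per-probe Spearman correlation of methylation with EMT score
#'
#' Descriptive ranking (no multiple-testing adjustment): rho between each
#' probe's beta values and the EMT score, sorted by decreasing rho so that
#' strongly positively score-coupled probes lead the table.
#'
#' @param beta Numeric matrix, samples x probes (usually pre-filtered with
#'   \code{\link{top_variance_probes}}).
#' @param scores EMT scores, matched to the rows of \code{beta}.
#' @return Data frame: probe, rho.
#' @export
probe_emt_correlation <- function(beta, scores) {
  beta <- as.matrix(beta)
  if (nrow(beta) != length(scores)) stop("beta rows must match scores")
  rho <- vapply(seq_len(ncol(beta)), function(j) {
    suppressWarnings(spearman_rho(beta[, j], scores, on_constant = "na"))
  }, numeric(1))
  out <- data.frame(probe = colnames(beta), rho = rho, stringsAsFactors = FALSE)
  out <- out[order(-out$rho, out$probe), , drop = FALSE]
  rownames(out) <- NULL
  out
}
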