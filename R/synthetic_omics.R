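#' Generate expression and methylome data with planted EMT mixing
#'
#' Each sample's marker-gene expression is a mixture of an epithelial and a
#' mesenchymal archetype weighted by a planted sarcoma fraction, plus
#' Gaussian noise (log10(FPKM+1) scale). A configured subset of methylation
#' probes is linearly coupled to the mixing fraction (emulating
#' miR-200-family promoter probes, whose methylation rises with mesenchymal
#' differentiation); the remaining probes are independent per-probe noise.
#'
#' @param n_samples Number of samples (default 97, the expression cohort
#'   size the generator emulates).
#' @param seed Integer seed.
#' @param sarcoma_fraction Optional planted mixing fractions (default
#'   uniform on 0.1-0.9).
#' @param noise_sd Expression noise standard deviation (default 0.4;
#'   0 gives exact rank ordering of EMT score by mixing fraction).
#' @param n_probes,n_coupled Total and score-coupled methylation probe counts
#'   (defaults 500 and 20).
#' @param beta_noise_sd Beta-value noise standard deviation (default 0.03).
#' @param markers Marker panel (gene, polarity).
#' @return List: expression (samples x 81 genes), beta (samples x probes),
#'   sarcoma_fraction (named), coupled_probes, markers.
#' @export
generate_expression_methylome <- function(n_samples = 97L, seed = 1L,
                                          sarcoma_fraction = NULL,
                                          noise_sd = 0.4, n_probes = 500L,
                                          n_coupled = 20L,
                                          beta_noise_sd = 0.03,
                                          markers = emt_marker_genes()) {
  with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n_samples))
    f <- if (is.null(sarcoma_fraction)) {
      stats::runif(n_samples, 0.1, 0.9)
    } else {
      rep_len(sarcoma_fraction, n_samples)
    }
    names(f) <- ids

    epi_arch <- ifelse(markers$polarity == "epithelial", 3.0, 0.5)
    mes_arch <- ifelse(markers$polarity == "epithelial", 0.5, 3.0)
    expr <- t(vapply(f, function(fi) {
      (1 - fi) * epi_arch + fi * mes_arch +
        stats::rnorm(nrow(markers), 0, noise_sd)
    }, numeric(nrow(markers))))
    dimnames(expr) <- list(ids, markers$gene)

    coupled <- sprintf("cg_mir200like_%02d", seq_len(n_coupled))
    uncoupled <- sprintf("cg%05d", seq_len(n_probes - n_coupled))
    base <- stats::runif(n_probes - n_coupled, 0.1, 0.9)
    beta <- matrix(0, n_samples, n_probes,
                   dimnames = list(ids, c(coupled, uncoupled)))
    for (j in seq_len(n_coupled)) {
      beta[, j] <- 0.15 + 0.6 * f + stats::rnorm(n_samples, 0, beta_noise_sd)
    }
    for (j in seq_len(n_probes - n_coupled)) {
      beta[, n_coupled + j] <- base[j] + stats::rnorm(n_samples, 0, beta_noise_sd)
    }
    beta <- pmin(pmax(beta, 0), 1)

    list(expression = expr, beta = beta, sarcoma_fraction = f,
         coupled_probes = coupled, markers = markers)
  })
}
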