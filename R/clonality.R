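#' Tumor purity from B-allele frequency in LOH regions
#'
#' In a region that has lost one parental allele by single-copy loss, a tumor
#' of purity p mixed with diploid normal shows a major-allele B-allele
#' frequency b = 1 / (2 - p), so p = 2 - 1/b. Under copy-neutral LOH the
#' relation is b = (1 + p) / 2, so p = 2b - 1. The estimate is the median of
#' per-region purities, clipped to (0, 1].
#'
#' @param baf Numeric vector of major-allele B-allele frequencies, one per
#'   LOH region; values must exceed 0.5 (b = 0.5 carries no LOH signal).
#' @param model \code{"single_copy_loss"} (default) or \code{"copy_neutral"}.
#' @param n_variants Optional number of LOH variants behind the estimate
#'   (bookkeeping only).
#' @return List: purity, per_region (numeric vector), n_loh_variants, model.
#' @export
estimate_purity <- function(baf, model = c("single_copy_loss", "copy_neutral"),
                            n_variants = length(baf)) {
  model <- match.arg(model)
  if (length(baf) == 0L) stop("no LOH region available: purity unestimable")
  if (any(baf <= 0.5 + 1e-12)) {
    stop("major-allele BAF must exceed 0.5 in an LOH region; purity unestimable")
  }
  if (any(baf > 1)) stop("BAF values must lie in (0.5, 1]")
  per_region <- if (model == "single_copy_loss") 2 - 1 / baf else 2 * baf - 1
  p <- stats::median(per_region)
  p <- min(max(p, .Machine$double.eps), 1)
  list(purity = p, per_region = per_region, n_loh_variants = n_variants,
       model = model)
}

#' Cancer cell fraction from VAF, purity and local copy number
#'
#' ccf = vaf * (p * n_t + (1 - p) * n_n) / (p * m) where p is tumor purity,
#' n_t / n_n the tumor / normal local total copy numbers and m the mutation
#' multiplicity. When \code{multiplicity} is NULL it is resolved per variant
#' as the value in 1..n_t minimizing |ccf - 1| among candidates with
#' ccf <= 1 + tolerance (falling back to the largest multiplicity when no
#' candidate satisfies the cap). A mutation is clonal when ccf >= 0.8.
#'
#' @param vaf Variant allele frequencies (vector).
#' @param purity Tumor purity in (0, 1].
#' @param tumor_cn Local tumor total copy number (vector or scalar, >= 1).
#' @param normal_cn Normal copy number (default 2).
#' @param multiplicity Integer multiplicities, or NULL to resolve.
#' @param tolerance Cap slack for multiplicity resolution (default 0.2).
#' @param clonal_cutoff CCF at or above which a mutation is clonal (default 0.8).
#' @return Data frame: ccf, multiplicity, clonal.
#' @export
compute_ccf <- function(vaf, purity, tumor_cn = 2L, normal_cn = 2L,
                        multiplicity = NULL, tolerance = 0.2,
                        clonal_cutoff = 0.8) {
  if (length(purity) != 1L || is.na(purity) || purity <= 0 || purity > 1) {
    stop("purity must be a single value in (0, 1]")
  }
  n <- length(vaf)
  tumor_cn <- rep_len(as.integer(tumor_cn), n)
  normal_cn <- rep_len(as.integer(normal_cn), n)
  if (any(tumor_cn < 1L)) stop("tumor copy number must be >= 1")
  denom_cn <- purity * tumor_cn + (1 - purity) * normal_cn
  if (is.null(multiplicity)) {
    multiplicity <- vapply(seq_len(n), function(i) {
      m_cand <- seq_len(tumor_cn[i])
      ccf_cand <- vaf[i] * denom_cn[i] / (purity * m_cand)
      ok <- ccf_cand <= 1 + tolerance
      if (any(ok)) m_cand[ok][which.min(abs(ccf_cand[ok] - 1))] else tumor_cn[i]
    }, integer(1))
  } else {
    multiplicity <- rep_len(as.integer(multiplicity), n)
    if (any(multiplicity < 1L | multiplicity > tumor_cn)) {
      stop("multiplicity must lie in 1..tumor_cn")
    }
  }
  ccf <- vaf * denom_cn / (purity * multiplicity)
  data.frame(ccf = ccf, multiplicity = multiplicity,
             clonal = ccf >= clonal_cutoff)
}

#' Trunk/branch partition of two components' variants
#'
#' Trunk mutations are shared between the carcinoma and sarcoma components
#' (set intersection on the exact-allele key); branch mutations are private
#' to one component. Counts drive rendered trunk/branch lengths.
#'
#' @param a,b Character vectors of variant keys, or variant data frames (keys
#'   taken via \code{\link{variant_key}}).
#' @return List: trunk, branch_a, branch_b (key vectors), counts (named
#'   integer), trunk_fraction = |trunk| / |union|.
#' @export
partition_trunk_branch <- function(a, b) {
  if (is.data.frame(a)) a <- variant_key(a)
  if (is.data.frame(b)) b <- variant_key(b)
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0L) stop("empty variant union: nothing to partition")
  trunk <- intersect(a, b)
  branch_a <- setdiff(a, b)
  branch_b <- setdiff(b, a)
  n_union <- length(union(a, b))
  list(
    trunk = trunk, branch_a = branch_a, branch_b = branch_b,
    counts = c(trunk = length(trunk), branch_a = length(branch_a),
               branch_b = length(branch_b)),
    trunk_fraction = length(trunk) / n_union
  )
}
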