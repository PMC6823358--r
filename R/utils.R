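# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Pyrimidine-normalized substitution class of an SNV
#'
#' Collapses the 12 substitutions to the 6 classes C>A, C>G, C>T, T>A, T>C,
#' T>G by complementing purine-reference changes.
#'
#' @param ref,alt Single-base reference and alternate alleles (vectors).
#' @return Character vector of classes (NA for non-SNVs).
#' @export
substitution_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep(NA_character_, length(ref))
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  r <- ref[is_snv]; a <- alt[is_snv]
  flip <- r %in% c("A", "G")
  r[flip] <- comp[r[flip]]
  a[flip] <- comp[a[flip]]
  out[is_snv] <- paste0(r, ">", a)
  out
}
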