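# Independent oracles, deliberately implemented from first principles and
# kept separate from the package code paths they check.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments.
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_obs <- sum(outer(x, y, ">"))
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2L, function(i) {
    sum(outer(pooled[i], pooled[-i], ">"))
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Minimal variant data frame builder for unit tests.
make_variants <- function(n = 1L, sample_id = "S1", chrom = "1",
                          pos = seq(1000L, length.out = n, by = 10L),
                          ref = "A", alt = "T", variant_class = "SNV",
                          gene = "GENEX", protein_change = "p.A100T",
                          consequence = "missense", vaf = 0.3, depth = 200,
                          mapping_quality = 60, context = NULL, ...) {
  if (n == 0L) {
    df <- data.frame(
      sample_id = character(0), component_id = character(0),
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), variant_class = character(0), gene = character(0),
      protein_change = character(0), consequence = character(0),
      vaf = numeric(0), depth = numeric(0), mapping_quality = numeric(0),
      origin = character(0), stringsAsFactors = FALSE
    )
    return(df)
  }
  df <- data.frame(
    sample_id = sample_id, component_id = "bulk", chrom = chrom,
    pos = as.integer(pos), ref = ref, alt = alt,
    variant_class = variant_class, gene = gene,
    protein_change = protein_change, consequence = consequence,
    vaf = vaf, depth = depth, mapping_quality = mapping_quality,
    origin = "somatic", stringsAsFactors = FALSE
  )
  if (!is.null(context)) df$context <- context
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# Minimal tumor profile for subtyping tests.
make_profile <- function(sample_id, variants = make_variants(0),
                         n_aberrant = 0L, msi_unstable = character(0)) {
  segs <- data.frame(
    sample_id = sample_id, chrom = as.character(1:22), start = 1L,
    end = 100000000L, log2_ratio = 0, integer_cn = 2L, baf = NA_real_,
    stringsAsFactors = FALSE
  )
  if (n_aberrant > 0L) {
    ab <- data.frame(
      sample_id = sample_id, chrom = as.character(rep(1:8, length.out = n_aberrant)),
      start = as.integer(60e6), end = as.integer(68e6),
      log2_ratio = 0.6, integer_cn = 3L, baf = NA_real_,
      stringsAsFactors = FALSE
    )
    # spread duplicated chromosomes across distinct slots
    ab$start <- ab$start + (seq_len(n_aberrant) %/% 9L) * 10000000L
    ab$end <- ab$start + as.integer(8e6) - 1L
    segs <- rbind(ab, segs)
  }
  panel <- setNames(rep(FALSE, 6L),
                    c("BAT25", "BAT26", "D2S123", "D5S346", "D17S250", "BAT40"))
  panel[msi_unstable] <- TRUE
  structure(list(sample_id = sample_id, variants = variants, segments = segs,
                 msi_panel = panel, germline = NULL, beta = NULL),
            class = "tumor_profile")
}
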