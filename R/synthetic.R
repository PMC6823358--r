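# Synthetic cohort generator. Emulates the statistical structure the
# subtyping and repair-annotation stages assume -- per-subtype mutation
# burdens and substitution spectra, copy-number burden with a shared
# high-burden aberration signature, MSI marker panels, promoter-methylation
# beta values, purity/read-depth forward simulation of VAFs -- with every
# observable derived from a recorded truth value. Coordinates live on a
# synthetic genome: 22 autosomes of 100 Mb whose reference base at position
# x is A/C/G/T for x mod 4 = 0/1/2/3, so reference context is reproducible
# without a genome file.

genome_base <- function(pos) c("A", "C", "G", "T")[(pos %% 4L) + 1L]

genome_context <- function(pos, flank = 6L) {
  vapply(pos, function(p) {
    paste(genome_base((p - flank):(p + flank)), collapse = "")
  }, character(1))
}

# position offsets (mod 4) that put the stated pyrimidine reference base at
# the variant position: C at pos %% 4 == 1, T at pos %% 4 == 3
spectrum_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
class_residue <- c("C>A" = 1L, "C>G" = 1L, "C>T" = 1L,
                   "T>A" = 3L, "T>C" = 3L, "T>G" = 3L)
class_alt <- c("C>A" = "A", "C>G" = "G", "C>T" = "T",
               "T>A" = "A", "T>C" = "C", "T>G" = "G")

#' Synthetic cohort generator configuration
#'
#' Defaults encode the study conditions the generator emulates: a 109-sample
#' cohort with subtype composition POLE 11 / MSI 24 / CNH 64 / CNL 10;
#' per-subtype SNV/indel/CNV counts drawn from two-piece log-uniform
#' distributions anchored at the published range and median (POLE SNVs
#' 190-1999 median 479; MSI indels 10-63 median 27; CNH CNVs median 17);
#' subtype-specific substitution spectra (T>C elevated in MSI, T>G in POLE);
#' conditional repair-lesion frequencies (MMR lesions in 22/24 MSI samples,
#' HR deficiency in 23/64 and non-HRD instability in 17/64 CNH samples);
#' tumor purity uniform on 0.3-0.9 and panel-like read depth 300.
#'
#' @param n_samples Cohort size (default 109).
#' @param subtype_counts Named integer vector over POLE/MSI/CNH/CNL summing
#'   to \code{n_samples}.
#' @param depth Mean sequencing depth for binomial read simulation.
#' @param purity_range Uniform range for tumor purity.
#' @param loh_regions,loh_depth Number of LOH regions per sample and the
#'   effective allele-count depth of the BAF estimate in each region (BAF in
#'   an LOH region aggregates reads over many heterozygous sites, hence the
#'   high default).
#' @param clonal_prob Probability a passenger mutation is clonal (CCF 1);
#'   subclonal CCFs are uniform on 0.15-0.75.
#' @param mmr_in_msi,hrd_in_cnh,nonhrd_in_cnh Conditional lesion frequencies.
#' @param recurrent_artifact_rate Per-sample probability of the planted
#'   cohort-recurrent FFPE artifact.
#' @return Config list (class \code{cohort_config}).
#' @export
cohort_config <- function(n_samples = 109L,
                          subtype_counts = c(POLE = 11L, MSI = 24L,
                                             CNH = 64L, CNL = 10L),
                          depth = 300L,
                          purity_range = c(0.3, 0.9),
                          loh_regions = 8L,
                          loh_depth = 2000L,
                          clonal_prob = 0.75,
                          mmr_in_msi = 22 / 24,
                          hrd_in_cnh = 23 / 64,
                          nonhrd_in_cnh = 17 / 64,
                          recurrent_artifact_rate = 0.35) {
  if (sum(subtype_counts) != n_samples) {
    stop("subtype counts must sum to n_samples")
  }
  if (!setequal(names(subtype_counts), c("POLE", "MSI", "CNH", "CNL"))) {
    stop("subtype_counts must be named POLE, MSI, CNH, CNL")
  }
  probs <- c(mmr_in_msi, hrd_in_cnh, nonhrd_in_cnh, recurrent_artifact_rate)
  if (any(probs < 0 | probs > 1) || hrd_in_cnh + nonhrd_in_cnh > 1) {
    stop("lesion probabilities must lie in [0,1] (HRD + non-HRD <= 1)")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    subtype_counts = subtype_counts,
    # c(min, median, max) anchors; CNV anchors for CNH/CNL are truncated to
    # keep the high/low burden classes identifiable (see methods vignette)
    counts = list(
      POLE = list(snv = c(190, 479, 1999), indel = c(1, 3, 56), cnv = c(0, 1, 28)),
      MSI = list(snv = c(8, 55, 207), indel = c(10, 27, 63), cnv = c(0, 2, 7)),
      CNH = list(snv = c(1, 6, 19), indel = c(0, 1, 6), cnv = c(9, 17, 48)),
      CNL = list(snv = c(1, 8, 30), indel = c(0, 1, 5), cnv = c(0, 2, 7))
    ),
    spectra = list(
      POLE = c(0.15, 0.05, 0.20, 0.05, 0.10, 0.45),  # T>G elevated
      MSI = c(0.10, 0.05, 0.25, 0.05, 0.45, 0.10),   # T>C elevated
      CNH = c(0.10, 0.10, 0.40, 0.10, 0.20, 0.10),
      CNL = c(0.10, 0.10, 0.40, 0.10, 0.20, 0.10)
    ),
    depth = as.integer(depth),
    purity_range = purity_range,
    loh_regions = as.integer(loh_regions),
    loh_depth = as.integer(loh_depth),
    clonal_prob = clonal_prob,
    mmr_in_msi = mmr_in_msi,
    hrd_in_cnh = hrd_in_cnh,
    nonhrd_in_cnh = nonhrd_in_cnh,
    mmr_split = c(MLH1_hyper = 12, germline = 5, somatic = 5) / 22,
    hrd_split = c(BRCA1_hyper = 5, RAD51C_hyper = 3, germline = 5, PTEN = 10) / 23,
    nonhrd_split = c(CCNE1 = 15, RB1 = 2) / 17,
    recurrent_artifact_rate = recurrent_artifact_rate,
    trunk_fraction = c(POLE = 0.35, MSI = 0.45, CNH = 56 / 74, CNL = 15 / 16)
  ), class = "cohort_config")
}

# two-piece log-uniform on [min, max] with the distribution median anchored
# at med: each half carries probability 1/2
rcount_anchored <- function(n, anchors) {
  lo <- anchors[1]; med <- anchors[2]; hi <- anchors[3]
  side_hi <- stats::runif(n) < 0.5
  u <- stats::runif(n)
  x <- ifelse(side_hi,
              exp(log(med + 1) + u * (log(hi + 1) - log(med + 1))) - 1,
              exp(log(lo + 1) + u * (log(med + 1) - log(lo + 1))) - 1)
  as.integer(round(x))
}

# largest-remainder apportionment of `total` over weights
apportion <- function(total, weights) {
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

amino_acids <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

empty_variant_frame <- function() {
  data.frame(
    sample_id = character(0), component_id = character(0), chrom = character(0),
    pos = integer(0), ref = character(0), alt = character(0),
    variant_class = character(0), gene = character(0),
    protein_change = character(0), consequence = character(0),
    vaf = numeric(0), depth = numeric(0), mapping_quality = numeric(0),
    origin = character(0), context = character(0), ccf_true = numeric(0),
    stringsAsFactors = FALSE
  )
}

variant_rows <- function(sample_id, gene, chrom, pos, ref, alt, variant_class,
                         consequence, protein_change, vaf, depth,
                         mapping_quality = 60, origin = "somatic",
                         component_id = "bulk", context = genome_context(pos),
                         ccf_true = NA_real_) {
  data.frame(
    sample_id = sample_id, component_id = component_id, chrom = chrom,
    pos = as.integer(pos), ref = ref, alt = alt, variant_class = variant_class,
    gene = gene, protein_change = protein_change, consequence = consequence,
    vaf = vaf, depth = depth, mapping_quality = mapping_quality,
    origin = origin, context = context, ccf_true = ccf_true,
    stringsAsFactors = FALSE
  )
}

# Fixed-position catalog of planted driver / lesion variants: deterministic
# keys, so they stand in for database-recurrent (whitelisted) mutations.
planted_catalog <- function(panel = panel_genes()) {
  g <- function(name) panel[panel$gene == name, , drop = FALSE]
  fixed <- function(gene, offset, consequence, protein_change,
                    indel = FALSE) {
    row <- g(gene)
    pos <- row$start + offset
    if (indel) {
      ref <- paste0(genome_base(pos), genome_base(pos + 1L))
      alt <- substr(ref, 1L, 1L)
      cls <- "indel"
    } else {
      ref <- genome_base(pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
      cls <- "SNV"
    }
    data.frame(gene = gene, chrom = row$chrom, pos = pos, ref = ref, alt = alt,
               variant_class = cls, consequence = consequence,
               protein_change = protein_change, stringsAsFactors = FALSE)
  }
  list(
    pole_hotspot = fixed("POLE", 858L, "missense", "p.P286R"),
    arid1a = fixed("ARID1A", 1758L, "truncating", "p.Q586*"),
    tp53 = fixed("TP53", 525L, "missense", "p.R175H"),
    mmr_somatic = list(
      MLH1 = fixed("MLH1", 901L, "truncating", "p.R301*"),
      MSH2 = fixed("MSH2", 1121L, "truncating", "p.Q374*"),
      MSH6 = fixed("MSH6", 3101L, "truncating", "p.R1034*"),
      PMS2 = fixed("PMS2", 401L, "truncating", "p.E134*")
    ),
    mmr_germline = list(
      MLH1 = fixed("MLH1", 306L, "truncating", "p.K102fs"),
      MSH2 = fixed("MSH2", 1121L, "truncating", "p.Q374*"),
      MSH6 = fixed("MSH6", 4001L, "splice", "p.?"),
      PMS2 = fixed("PMS2", 2192L, "truncating", "p.S731fs")
    ),
    hr_germline = list(
      BRCA1 = fixed("BRCA1", 5278L, "splice", "p.?"),
      BRCA2 = fixed("BRCA2", 4340L, "truncating", "p.V1447*"),
      ATM = fixed("ATM", 2250L, "truncating", "p.R750*"),
      RAD50 = fixed("RAD50", 1300L, "truncating", "p.E434*"),
      BLM = fixed("BLM", 3168L, "truncating", "p.K1056fs")
    ),
    pten_somatic = fixed("PTEN", 389L, "missense", "p.R130G"),
    recurrent_artifact = fixed("CSG001", 501L, "missense", "p.A167V")
  )
}

#' Whitelist of database-recurrent variant keys used by the generator
#'
#' Keys of all planted driver and repair-lesion variants; these stand in for
#' mutations recurrent in public somatic-mutation databases and are exempt
#' from the cohort-recurrence FFPE filter.
#'
#' @return Character vector of variant keys.
#' @export
planted_whitelist <- function() {
  cat_ <- planted_catalog()
  flat <- c(list(cat_$pole_hotspot, cat_$arid1a, cat_$tp53, cat_$pten_somatic),
            cat_$mmr_somatic, cat_$mmr_germline, cat_$hr_germline)
  unique(unlist(lapply(flat, variant_key)))
}

# copy-number slot grid: 8 disjoint 8-Mb slots per chromosome
cn_slots <- function() {
  starts <- c(5, 15, 25, 35, 60, 70, 80, 90) * 1e6
  out <- expand.grid(chrom = as.character(1:22), start = starts,
                     stringsAsFactors = FALSE)
  out$start <- as.integer(out$start)
  out$end <- out$start + as.integer(8e6) - 1L
  # shared high-burden signature: q-arm slot at 60 Mb, gains on chr 1-8,
  # losses on chr 9-16; sig_rank orders the slots by recurrence, so CNH
  # samples accumulate them in a fixed order (arm-level changes in
  # copy-number-driven tumors are strongly recurrent)
  out$signature <- out$start == 60e6 & out$chrom %in% as.character(1:16)
  out$sig_gain <- out$signature & out$chrom %in% as.character(1:8)
  out$sig_rank <- NA_integer_
  out$sig_rank[out$signature] <- as.integer(out$chrom[out$signature])
  out
}

forward_vaf <- function(ccf, purity, depth_mean, multiplicity = 1,
                        tumor_cn = 2, normal_cn = 2) {
  evaf <- ccf * purity * multiplicity / (purity * tumor_cn + (1 - purity) * normal_cn)
  d <- pmax(stats::rpois(length(ccf), depth_mean), 50L)
  alt <- stats::rbinom(length(ccf), d, evaf)
  list(vaf = alt / d, depth = d)
}

random_passengers <- function(sample_id, n_snv, n_indel, spectrum, pool,
                              purity, depth_mean, clonal_prob) {
  n <- n_snv + n_indel
  if (n == 0L) return(empty_variant_frame())
  gi <- sample(nrow(pool), n, replace = TRUE)
  is_snv <- c(rep(TRUE, n_snv), rep(FALSE, n_indel))
  cls <- sample(spectrum_classes, n, replace = TRUE, prob = spectrum)
  # position with the class's pyrimidine reference base at the variant site
  res <- ifelse(is_snv, class_residue[cls], 0L)
  offset <- sample.int(4990L, n, replace = TRUE) * 4L + res - (pool$start[gi] %% 4L)
  pos <- pool$start[gi] + offset + 4L
  ref <- ifelse(is_snv, genome_base(pos),
                paste0(genome_base(pos), genome_base(pos + 1L)))
  alt <- ifelse(is_snv, class_alt[cls], genome_base(pos))
  consequence <- ifelse(
    is_snv,
    sample(c("missense", "synonymous", "truncating", "inframe", "splice"),
           n, replace = TRUE, prob = c(0.55, 0.15, 0.15, 0.05, 0.10)),
    sample(c("truncating", "inframe", "splice"),
           n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  )
  protein_change <- sprintf("p.%s%d%s",
                            sample(amino_acids, n, replace = TRUE),
                            sample.int(700L, n, replace = TRUE),
                            sample(amino_acids, n, replace = TRUE))
  ccf <- ifelse(stats::runif(n) < clonal_prob, 1, stats::runif(n, 0.15, 0.75))
  reads <- forward_vaf(ccf, purity, depth_mean)
  out <- variant_rows(
    sample_id = sample_id, gene = pool$gene[gi], chrom = pool$chrom[gi],
    pos = pos, ref = ref, alt = alt,
    variant_class = ifelse(is_snv, "SNV", "indel"),
    consequence = consequence, protein_change = protein_change,
    vaf = reads$vaf, depth = reads$depth,
    mapping_quality = stats::runif(n, 40, 60), ccf_true = ccf
  )
  out[!duplicated(variant_key(out)), , drop = FALSE]
}

planted_variant <- function(sample_id, spec, vaf, depth, ccf = 1,
                            origin = "somatic") {
  variant_rows(
    sample_id = sample_id, gene = spec$gene, chrom = spec$chrom,
    pos = spec$pos, ref = spec$ref, alt = spec$alt,
    variant_class = spec$variant_class, consequence = spec$consequence,
    protein_change = spec$protein_change, vaf = vaf, depth = depth,
    origin = origin, ccf_true = ccf
  )
}

beta_probe_names <- function(gene) paste0(gene, "_p", 1:8)

# probes 1-5 are DMR-informative (near 0 unless hypermethylated), 6-8 are
# uninformative low-range noise
gene_beta_values <- function(gene, hypermethylated) {
  dmr <- if (hypermethylated) stats::runif(5, 0.55, 0.85) else stats::runif(5, 0.01, 0.08)
  stats::setNames(c(dmr, stats::runif(3, 0.02, 0.06)), beta_probe_names(gene))
}

assign_lesions <- function(subtype, n_sub, config) {
  # deterministic per-subtype lesion plan: mechanism label per sample slot
  plan <- rep("none", n_sub)
  if (subtype == "MSI") {
    n_lesion <- round(config$mmr_in_msi * n_sub)
    mech <- apportion(n_lesion, config$mmr_split)
    plan[seq_len(n_lesion)] <- rep(names(mech), mech)
  } else if (subtype == "CNH") {
    n_hrd <- round(config$hrd_in_cnh * n_sub)
    n_non <- round(config$nonhrd_in_cnh * n_sub)
    mech_h <- apportion(n_hrd, config$hrd_split)
    mech_n <- apportion(n_non, config$nonhrd_split)
    plan[seq_len(n_hrd + n_non)] <- c(rep(names(mech_h), mech_h),
                                      rep(names(mech_n), mech_n))
  }
  plan
}

lesion_truth_label <- function(mech) {
  switch(mech,
    MLH1_hyper = c("MMR", "promoter_hypermethylation", "MLH1"),
    germline = c(NA, "germline_plus_LOH", NA),  # gene filled by caller
    somatic = c("MMR", "somatic_biallelic", NA),
    BRCA1_hyper = c("HR", "promoter_hypermethylation", "BRCA1"),
    RAD51C_hyper = c("HR", "promoter_hypermethylation", "RAD51C"),
    PTEN = c("HR", "somatic_PTEN", "PTEN"),
    CCNE1 = c("nonHRD", "CCNE1_amplification", "CCNE1"),
    RB1 = c("nonHRD", "RB1_homozygous_deletion", "RB1"),
    none = c("none", NA, NA)
  )
}

#' Generate a synthetic carcinosarcoma cohort with recorded truth
#'
#' Produces one tumor profile per sample (per-caller somatic variant tables,
#' clean somatic variants, germline variants, copy-number segments with a
#' diploid baseline, the 6-marker MSI panel, promoter beta values for
#' MLH1/BRCA1/RAD51C, LOH-region BAFs, clinical covariates) together with a
#' truth table recording subtype, purity, ploidy, planted repair lesion and
#' burden counts. Deterministic given the seed.
#'
#' @param config Configuration from \code{\link{cohort_config}}.
#' @param seed Integer seed.
#' @return List (class \code{synthetic_cohort}): profiles (list), truth
#'   (data frame), whitelist (planted database-recurrent keys), config.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    panel <- panel_genes()
    cat_ <- planted_catalog(panel)
    sensitive <- c("POLE", "PTEN", "ARID1A", "TP53", "PPP2R1A",
                   repair_gene_sets()$MMR, repair_gene_sets()$HR,
                   "CCNE1", "RB1", "NF1", "CSG001")
    pool <- panel[!(panel$gene %in% sensitive), , drop = FALSE]
    slots <- cn_slots()

    subtype <- rep(names(config$subtype_counts), config$subtype_counts)
    n <- length(subtype)
    ids <- sprintf("CS%03d", seq_len(n))
    lesions <- unlist(lapply(names(config$subtype_counts), function(st) {
      assign_lesions(st, config$subtype_counts[[st]], config)
    }))
    mmr_genes <- repair_gene_sets()$MMR
    hr_genes <- names(cat_$hr_germline)

    profiles <- vector("list", n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      st <- subtype[i]
      purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
      ploidy <- if (st == "CNH") stats::rnorm(1, 3.1, 0.3) else stats::rnorm(1, 2.0, 0.1)
      anchors <- config$counts[[st]]
      n_snv <- max(1L, rcount_anchored(1, anchors$snv))
      n_indel <- rcount_anchored(1, anchors$indel)
      n_cnv <- rcount_anchored(1, anchors$cnv)

      vars <- random_passengers(ids[i], n_snv, n_indel, config$spectra[[st]],
                                pool, purity, config$depth, config$clonal_prob)
      germ <- empty_variant_frame()
      germ$population_maf <- numeric(0)
      germ$pathogenicity <- character(0)

      # subtype-defining and driver mutations (always fully supported)
      planted <- list()
      if (st == "POLE") {
        reads <- forward_vaf(1, purity, config$depth)
        planted$pole <- planted_variant(ids[i], cat_$pole_hotspot,
                                        reads$vaf, reads$depth)
      }
      if (st %in% c("POLE", "MSI")) {
        reads <- forward_vaf(1, purity, config$depth)
        planted$driver <- planted_variant(ids[i], cat_$arid1a,
                                          reads$vaf, reads$depth)
      }
      if (st == "CNH") {
        reads <- forward_vaf(1, purity, config$depth)
        planted$driver <- planted_variant(ids[i], cat_$tp53,
                                          reads$vaf, reads$depth)
      }

      # repair lesion planting
      mech <- lesions[i]
      lesion_gene <- NA_character_
      hyper <- c(MLH1 = FALSE, BRCA1 = FALSE, RAD51C = FALSE)
      lesion_segments <- NULL
      if (mech == "MLH1_hyper") hyper["MLH1"] <- TRUE
      if (mech == "BRCA1_hyper") hyper["BRCA1"] <- TRUE
      if (mech == "RAD51C_hyper") hyper["RAD51C"] <- TRUE
      if (mech == "germline" && st == "MSI") {
        lesion_gene <- mmr_genes[(i %% length(mmr_genes)) + 1L]
        g <- planted_variant(ids[i], cat_$mmr_germline[[lesion_gene]],
                             vaf = stats::runif(1, 0.7, 0.9), depth = 100,
                             origin = "germline")
        g$population_maf <- 1e-4
        g$pathogenicity <- "pathogenic"
        germ <- rbind(germ, g)
      }
      if (mech == "germline" && st == "CNH") {
        lesion_gene <- hr_genes[(i %% length(hr_genes)) + 1L]
        g <- planted_variant(ids[i], cat_$hr_germline[[lesion_gene]],
                             vaf = stats::runif(1, 0.7, 0.9), depth = 100,
                             origin = "germline")
        g$population_maf <- 1e-4
        g$pathogenicity <- "pathogenic"
        germ <- rbind(germ, g)
      }
      if (mech == "somatic") {
        lesion_gene <- mmr_genes[(i %% length(mmr_genes)) + 1L]
        planted$lesion <- planted_variant(
          ids[i], cat_$mmr_somatic[[lesion_gene]],
          vaf = stats::runif(1, 0.65, 0.85), depth = config$depth
        )
      }
      if (mech == "PTEN") {
        reads <- forward_vaf(1, purity, config$depth)
        planted$lesion <- planted_variant(ids[i], cat_$pten_somatic,
                                          reads$vaf, reads$depth)
      }
      if (mech == "CCNE1") {
        gr <- panel[panel$gene == "CCNE1", ]
        lesion_segments <- data.frame(
          sample_id = ids[i], chrom = gr$chrom,
          start = gr$start - 500000L, end = gr$end + 500000L,
          log2_ratio = 2.0, integer_cn = 8L, baf = NA_real_,
          stringsAsFactors = FALSE
        )
      }
      if (mech == "RB1") {
        gr <- panel[panel$gene == "RB1", ]
        lesion_segments <- data.frame(
          sample_id = ids[i], chrom = gr$chrom,
          start = gr$start - 500000L, end = gr$end + 500000L,
          log2_ratio = -3.0, integer_cn = 0L, baf = NA_real_,
          stringsAsFactors = FALSE
        )
      }

      # benign germline background (filtered out downstream)
      bg <- random_passengers(ids[i], 3L, 0L, config$spectra[[st]], pool,
                              1, 100, 1)
      bg$origin <- "germline"
      bg$vaf <- stats::runif(nrow(bg), 0.4, 0.6)
      bg$population_maf <- stats::runif(nrow(bg), 0.05, 0.4)
      bg$pathogenicity <- "benign"
      germ <- rbind(germ, bg)

      clean <- do.call(rbind, c(list(vars), unname(planted)))
      clean <- clean[!duplicated(variant_key(clean)), , drop = FALSE]

      # copy-number segments: diploid baseline + aberrant slots (+ lesion)
      baseline <- data.frame(
        sample_id = ids[i], chrom = as.character(1:22), start = 1L,
        end = 100000000L, log2_ratio = stats::rnorm(22, 0, 0.02),
        integer_cn = 2L, baf = NA_real_, stringsAsFactors = FALSE
      )
      ab <- NULL
      if (n_cnv > 0L) {
        if (st == "CNH") {
          sig_idx <- which(slots$signature)[order(slots$sig_rank[slots$signature])]
          n_sig <- min(length(sig_idx), n_cnv)
          pick_sig <- sig_idx[seq_len(n_sig)]
          pick_rand <- sample(which(!slots$signature), n_cnv - n_sig)
          picked <- slots[c(pick_sig, pick_rand), , drop = FALSE]
          gain <- ifelse(picked$signature, picked$sig_gain,
                         stats::runif(nrow(picked)) < 0.5)
        } else {
          picked <- slots[sample(which(!slots$signature), min(n_cnv, sum(!slots$signature))), , drop = FALSE]
          gain <- stats::runif(nrow(picked)) < 0.5
        }
        ab <- data.frame(
          sample_id = ids[i], chrom = picked$chrom, start = picked$start,
          end = picked$end,
          log2_ratio = ifelse(gain, 1, -1) * stats::runif(nrow(picked), 0.45, 0.8),
          integer_cn = ifelse(gain, 3L, 1L), baf = NA_real_,
          stringsAsFactors = FALSE
        )
      }
      segments <- rbind(lesion_segments, ab, baseline)

      # MSI marker panel
      panel_flags <- stats::setNames(rep(FALSE, 6L), msi_markers)
      if (st == "MSI") {
        k <- 2L + stats::rbinom(1, 4, 0.5)
        panel_flags[sample(msi_markers, k)] <- TRUE
      } else if (stats::runif(1) < 0.08) {
        panel_flags[sample(msi_markers, 1)] <- TRUE
      }

      # promoter methylation
      beta <- list(
        MLH1 = gene_beta_values("MLH1", hyper["MLH1"]),
        BRCA1 = gene_beta_values("BRCA1", hyper["BRCA1"]),
        RAD51C = gene_beta_values("RAD51C", hyper["RAD51C"])
      )

      # LOH-region BAF observations for purity estimation
      b_true <- 1 / (2 - purity)
      loh_baf <- stats::rbinom(config$loh_regions, config$loh_depth, b_true) /
        config$loh_depth

      # per-caller tables: clean calls + planted artifacts + caller noise
      caller_calls <- make_caller_calls(ids[i], clean, planted, pool, cat_,
                                        config)

      hist_ca <- if (st == "CNH") {
        sample(c("serous", "endometrioid"), 1, prob = c(0.7, 0.3))
      } else {
        sample(c("endometrioid", "serous"), 1, prob = c(0.85, 0.15))
      }
      age <- round(stats::rnorm(1, if (st == "CNH") 68 else 58, 8))
      sarcoma_fraction <- stats::runif(1, 0.1, 0.9)

      if (mech != "none" && is.na(lesion_truth_label(mech)[3])) {
        lg <- lesion_gene
      } else {
        lg <- lesion_truth_label(mech)[3]
      }
      tl <- lesion_truth_label(mech)
      pathway <- if (is.na(tl[1])) (if (st == "MSI") "MMR" else "HR") else tl[1]

      profiles[[i]] <- structure(list(
        sample_id = ids[i], caller_calls = caller_calls, variants = clean,
        germline = germ, segments = segments, msi_panel = panel_flags,
        beta = beta, loh_baf = loh_baf, age = age,
        histology_carcinoma = hist_ca, sarcoma_fraction = sarcoma_fraction
      ), class = "tumor_profile")
      truth_rows[[i]] <- data.frame(
        sample_id = ids[i], subtype = st, purity = purity, ploidy = ploidy,
        n_snv = sum(clean$variant_class == "SNV"),
        n_indel = sum(clean$variant_class == "indel"),
        n_cnv = n_cnv + as.integer(!is.null(lesion_segments)),
        repair_pathway = pathway, repair_mechanism = tl[2], repair_gene = lg,
        msi_unstable = sum(panel_flags), age = age,
        histology_carcinoma = hist_ca, sarcoma_fraction = sarcoma_fraction,
        stringsAsFactors = FALSE
      )
    }
    structure(list(
      profiles = profiles, truth = do.call(rbind, truth_rows),
      whitelist = planted_whitelist(), config = config
    ), class = "synthetic_cohort")
  })
}

# Per-caller variant tables. Clean variants are detected by all 3 callers
# (planted drivers/lesions always) or a random pair; planted FFPE artifacts
# (low mapping quality, shallow depth, homopolymer-adjacent indel, cohort-
# recurrent allele) are supported by 2 callers so they survive consensus and
# must be removed by the FFPE filters; each caller adds private noise calls
# removed by consensus.
make_caller_calls <- function(sample_id, clean, planted, pool, cat_, config) {
  callers <- c("caller1", "caller2", "caller3")
  planted_keys <- unlist(lapply(planted, variant_key))
  keys <- variant_key(clean)
  support <- lapply(seq_len(nrow(clean)), function(j) {
    if (keys[j] %in% planted_keys || stats::runif(1) < 0.7) callers
    else sample(callers, 2L)
  })

  artifacts <- list()
  art_pos <- pool$start[sample(nrow(pool), 4L)] + sample.int(15000L, 4L)
  mk_art <- function(pos, gene_idx, vaf, depth, mq, indel = FALSE,
                     context = NULL) {
    ref <- if (indel) paste0(genome_base(pos), genome_base(pos + 1L)) else genome_base(pos)
    alt <- if (indel) substr(ref, 1, 1) else setdiff(c("A", "C", "G", "T"), ref)[1]
    v <- variant_rows(
      sample_id = sample_id, gene = pool$gene[gene_idx], chrom = pool$chrom[gene_idx],
      pos = pos, ref = ref, alt = alt,
      variant_class = if (indel) "indel" else "SNV",
      consequence = "missense", protein_change = "p.L100F",
      vaf = vaf, depth = depth, mapping_quality = mq
    )
    if (!is.null(context)) v$context <- context
    v
  }
  gi <- sample(nrow(pool), 4L)
  artifacts$low_mq <- mk_art(art_pos[1], gi[1], 0.1, 200, 10)
  artifacts$shallow <- mk_art(art_pos[2], gi[2], 0.2, 30, 55)
  artifacts$homopolymer <- mk_art(art_pos[3], gi[3], 0.15, 150, 55,
                                  indel = TRUE, context = "CGAAAAACGTACG")
  if (stats::runif(1) < config$recurrent_artifact_rate) {
    ra <- planted_variant(sample_id, cat_$recurrent_artifact, 0.12, 180)
    artifacts$recurrent <- ra
  }

  lapply(stats::setNames(callers, callers), function(cl) {
    rows <- clean[vapply(support, function(s) cl %in% s, logical(1)), , drop = FALSE]
    # artifacts supported by callers 1 and 2 only (2-of-3: they survive
    # consensus and must fall to the FFPE filters)
    if (cl %in% c("caller1", "caller2") && length(artifacts)) {
      rows <- rbind(rows, do.call(rbind, unname(artifacts)))
    }
    # private caller noise (single-caller calls, removed by consensus)
    noise_idx <- sample(nrow(pool), 2L)
    noise_pos <- pool$start[noise_idx] + sample.int(15000L, 2L)
    noise <- mk_art(noise_pos[1], noise_idx[1], 0.08, 120, 50)
    noise2 <- mk_art(noise_pos[2], noise_idx[2], 0.07, 130, 50)
    out <- rbind(rows, noise, noise2)
    out[!duplicated(variant_key(out)), , drop = FALSE]
  })
}

#' Run caller consensus and FFPE filtering over a synthetic cohort
#'
#' Applies the 2-of-3 consensus merge per sample, computes cohort-wide
#' recurrence counts on the merged calls, and applies the five FFPE noise
#' filters (with per-sample chromosome modal ploidy from the segments and the
#' cohort whitelist). Germline variants are filtered to the significant set.
#' The processed variant tables replace \code{variants}/\code{germline} in
#' the returned profiles.
#'
#' @param cohort \code{synthetic_cohort} object (or a list with profiles and
#'   whitelist).
#' @param recurrence_threshold Cohort-recurrence removal threshold (default 2).
#' @return The cohort with processed profiles.
#' @export
process_cohort <- function(cohort, recurrence_threshold = 2L) {
  merged <- lapply(cohort$profiles, function(p) consensus_merge(p$caller_calls))
  rec <- cohort_recurrence_counts(do.call(rbind, merged))
  cohort$profiles <- lapply(seq_along(cohort$profiles), function(i) {
    p <- cohort$profiles[[i]]
    pl <- chrom_modal_ploidy(p$segments)
    p$variants <- apply_ffpe_filters(
      merged[[i]], cohort_recurrence = rec, whitelist = cohort$whitelist,
      chrom_ploidy = pl, recurrence_threshold = recurrence_threshold
    )
    p$germline <- filter_germline(p$germline)
    p
  })
  cohort
}
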