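beta_list <- function(mlh1 = 0.03, brca1 = 0.03, rad51c = 0.03) {
  mk <- function(gene, level) {
    stats::setNames(c(rep(level, 5), rep(0.04, 3)), paste0(gene, "_p", 1:8))
  }
  list(MLH1 = mk("MLH1", mlh1), BRCA1 = mk("BRCA1", brca1),
       RAD51C = mk("RAD51C", rad51c))
}

repair_profile <- function(sample_id, somatic = make_variants(0),
                           germline = NULL, beta = beta_list(),
                           lesion_seg = NULL) {
  segs <- data.frame(
    sample_id = sample_id, chrom = as.character(1:22), start = 1L,
    end = 100000000L, log2_ratio = 0, integer_cn = 2L, baf = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(lesion_seg)) segs <- rbind(lesion_seg, segs)
  structure(list(sample_id = sample_id, variants = somatic,
                 germline = germline, segments = segs, beta = beta),
            class = "tumor_profile")
}

test_that("DMR probe selection applies range and median thresholds", {
  m <- rbind(a = c(0.05, 0.05, 0.30), b = c(0.55, 0.05, 0.80),
             c = c(0.04, 0.05, 0.28), d = c(0.06, 0.06, 0.31))
  colnames(m) <- c("p1", "p2", "p3")
  # p1: range 0.51, median 0.055 -> selected; p2 constant-ish -> out;
  # p3: range 0.52 but median 0.305 -> out
  expect_equal(select_dmr_probes(m), "p1")
  expect_warning(out <- select_dmr_probes(m[, 2, drop = FALSE]), "unassessable")
  expect_length(out, 0)
})

test_that("hypermethylation cutoff is mean beta >= 0.4 and monotone", {
  expect_true(call_hypermethylation(c(0.5, 0.6)))
  expect_false(call_hypermethylation(c(0, 0)))
  expect_true(call_hypermethylation(c(0.4, 0.4)))   # boundary inclusive
  expect_error(call_hypermethylation(numeric(0)), "empty")
  set.seed(8)
  for (i in 1:20) {
    b <- runif(6)
    if (call_hypermethylation(b)) {
      bumped <- pmin(b + runif(6, 0, 0.3), 1)
      expect_true(call_hypermethylation(bumped))
    }
  }
})

test_that("copy-number classes follow the integer thresholds", {
  expect_equal(copy_number_class(c(0, 1, 2, 3, 5, 6, 9)),
               c("homozygous_deletion", "loss", "neutral", "gain", "gain",
                 "amplification", "amplification"))
  expect_error(copy_number_class(-1))
})

test_that("repair annotation assigns the planted mechanisms", {
  mlh1_hyper <- repair_profile("S1", beta = beta_list(mlh1 = 0.7))
  brca2_germ <- repair_profile(
    "S2",
    germline = make_variants(1, gene = "BRCA2", consequence = "truncating",
                             vaf = 0.8, pathogenicity = "pathogenic",
                             population_maf = 1e-4)
  )
  ccne1_gene <- panel_genes()[panel_genes()$gene == "CCNE1", ]
  ccne1 <- repair_profile("S3", lesion_seg = data.frame(
    sample_id = "S3", chrom = ccne1_gene$chrom,
    start = ccne1_gene$start - 100000L, end = ccne1_gene$end + 100000L,
    log2_ratio = 2, integer_cn = 8L, baf = NA_real_, stringsAsFactors = FALSE
  ))
  none <- repair_profile("S4")
  out <- annotate_repair_cohort(list(mlh1_hyper, brca2_germ, ccne1, none))
  expect_equal(out$pathway, c("MMR", "HR", "nonHRD", "none"))
  expect_equal(out$mechanism[1:3],
               c("promoter_hypermethylation", "germline_plus_LOH",
                 "CCNE1_amplification"))
  expect_equal(out$gene[1:3], c("MLH1", "BRCA2", "CCNE1"))
  expect_true(is.na(out$mechanism[4]))
})

test_that("somatic MMR lesions require biallelic evidence by default", {
  single_hit <- repair_profile(
    "S1", somatic = make_variants(1, gene = "MSH2", consequence = "truncating",
                                  vaf = 0.3)
  )
  loh_hit <- repair_profile(
    "S2", somatic = make_variants(1, gene = "MSH2", consequence = "truncating",
                                  vaf = 0.7)
  )
  out <- annotate_repair_cohort(list(single_hit, loh_hit))
  expect_equal(out$pathway, c("none", "MMR"))
  relaxed <- annotate_repair_cohort(list(single_hit), require_biallelic = FALSE)
  expect_equal(relaxed$pathway, "MMR")
})

test_that("somatic PTEN counts as HR evidence", {
  pten <- repair_profile("S1", somatic = make_variants(1, gene = "PTEN"))
  out <- annotate_repair_cohort(list(pten, repair_profile("S2")))
  expect_equal(out$pathway[1], "HR")
  expect_equal(out$mechanism[1], "somatic_PTEN")
})

test_that("mutual exclusivity: MMR outranks HR outranks nonHRD", {
  ccne1_gene <- panel_genes()[panel_genes()$gene == "CCNE1", ]
  multi <- repair_profile(
    "S1", beta = beta_list(mlh1 = 0.7, brca1 = 0.7),
    lesion_seg = data.frame(
      sample_id = "S1", chrom = ccne1_gene$chrom,
      start = ccne1_gene$start - 100000L, end = ccne1_gene$end + 100000L,
      log2_ratio = 2, integer_cn = 8L, baf = NA_real_, stringsAsFactors = FALSE
    )
  )
  # enough unmethylated samples that the DMR probes pass the median criterion
  cohort <- c(list(multi), lapply(paste0("S", 2:6), repair_profile))
  out <- annotate_repair_cohort(cohort)
  expect_equal(out$pathway[1], "MMR")
  expect_match(out$co_occurring[1], "HR/promoter_hypermethylation/BRCA1")
  expect_match(out$co_occurring[1], "nonHRD/CCNE1_amplification")
  expect_equal(sum(!is.na(out$pathway)), 6)  # exactly one call per sample
})

test_that("planted repair lesions are recovered across a synthetic cohort", {
  co <- process_cohort(generate_cohort(cohort_config(), seed = 17))
  calls <- annotate_repair_cohort(co$profiles)
  tt <- co$truth
  same <- calls$pathway == tt$repair_pathway &
    (mapply(identical, calls$mechanism, tt$repair_mechanism)) &
    (mapply(identical, calls$gene, tt$repair_gene))
  expect_gte(mean(same), 0.99)
})
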