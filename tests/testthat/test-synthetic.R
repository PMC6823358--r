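small_config <- function() {
  cohort_config(n_samples = 16L,
                subtype_counts = c(POLE = 2L, MSI = 4L, CNH = 8L, CNL = 2L))
}

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(small_config(), seed = 9)
  b <- generate_cohort(small_config(), seed = 9)
  expect_identical(a$truth, b$truth)
  expect_identical(a$profiles[[3]]$variants, b$profiles[[3]]$variants)
  expect_identical(a$profiles[[5]]$caller_calls, b$profiles[[5]]$caller_calls)
  c_ <- generate_cohort(small_config(), seed = 10)
  expect_false(identical(a$truth$purity, c_$truth$purity))
})

test_that("config validation rejects inconsistent proportions", {
  expect_error(cohort_config(n_samples = 10,
                             subtype_counts = c(POLE = 1, MSI = 2, CNH = 3,
                                                CNL = 3)),
               "sum")
  expect_error(cohort_config(mmr_in_msi = 1.4), "probabilities")
})

test_that("burden medians anchor to the published per-subtype values", {
  set.seed(33)
  draws <- csgenomics:::rcount_anchored(2000, c(190, 479, 1999))
  expect_lt(abs(median(draws) - 479) / 479, 0.2)
  draws_msi <- csgenomics:::rcount_anchored(2000, c(10, 27, 63))
  expect_lt(abs(median(draws_msi) - 27) / 27, 0.2)
  expect_true(all(draws >= 189 & draws <= 2000))
})

test_that("subtype-defining observables hold by construction", {
  co <- generate_cohort(small_config(), seed = 13)
  tt <- co$truth
  for (i in seq_len(nrow(tt))) {
    p <- co$profiles[[i]]
    if (tt$subtype[i] == "MSI") {
      expect_gte(sum(p$msi_panel), 2)
    } else {
      expect_lte(sum(p$msi_panel), 1)
    }
    if (tt$subtype[i] == "POLE") {
      expect_false(is.null(call_pole(p$variants)))
    }
  }
})

test_that("per-subtype burden ranks mirror the published pattern", {
  co <- generate_cohort(cohort_config(), seed = 29)
  tt <- co$truth
  med <- function(v, st) median(v[tt$subtype == st])
  expect_true(med(tt$n_snv, "POLE") > max(med(tt$n_snv, "MSI"),
                                          med(tt$n_snv, "CNH"),
                                          med(tt$n_snv, "CNL")))
  expect_true(med(tt$n_indel, "MSI") > max(med(tt$n_indel, "POLE"),
                                           med(tt$n_indel, "CNH"),
                                           med(tt$n_indel, "CNL")))
  expect_true(med(tt$n_cnv, "CNH") > max(med(tt$n_cnv, "POLE"),
                                         med(tt$n_cnv, "MSI"),
                                         med(tt$n_cnv, "CNL")))
})

test_that("substitution spectra carry the subtype signatures", {
  co <- generate_cohort(cohort_config(), seed = 19)
  tt <- co$truth
  frac <- function(st, cls) {
    v <- do.call(rbind, lapply(co$profiles[tt$subtype == st],
                               function(p) p$variants))
    sc <- substitution_class(v$ref, v$alt)
    mean(sc == cls, na.rm = TRUE)
  }
  expect_gt(frac("MSI", "T>C"), frac("CNH", "T>C"))
  expect_gt(frac("POLE", "T>G"), frac("CNH", "T>G"))
})

test_that("full round trip recovers subtypes at high accuracy", {
  accs <- vapply(1:3, function(s) {
    co <- process_cohort(generate_cohort(cohort_config(), seed = s))
    calls <- classify_cohort(co$profiles, reps = 500, seed = s)
    mean(co$truth$subtype == calls$label)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("biphasic tumors carry the planted trunk fraction", {
  b1 <- generate_biphasic("CNL", seed = 2, trunk_fraction = 1, n_total = 30)
  expect_setequal(variant_key(b1$carcinoma), variant_key(b1$sarcoma))
  pt <- partition_trunk_branch(b1$carcinoma, b1$sarcoma)
  expect_equal(pt$trunk_fraction, 1)
  # round trip: recovered fraction equals the realized planted fraction
  for (s in 1:5) {
    b <- generate_biphasic("CNH", seed = s, n_total = 80)
    pt <- partition_trunk_branch(b$carcinoma, b$sarcoma)
    expect_equal(pt$trunk_fraction, b$truth$trunk_fraction_realized,
                 tolerance = 1e-12)
  }
  # realized fractions concentrate around the planted probability
  fr <- vapply(1:30, function(s) {
    generate_biphasic("CNL", seed = s, n_total = 16)$truth$trunk_fraction_realized
  }, numeric(1))
  f <- 15 / 16
  expect_lt(abs(mean(fr) - f), 3 * sqrt(f * (1 - f) / 16) / sqrt(30))
})

test_that("drivers sit on the trunk for copy-number subtypes", {
  b <- generate_biphasic("CNL", seed = 7, n_total = 40)
  expect_true(all(b$drivers$location == "trunk"))
})

test_that("multi-region generation is deterministic and self-consistent", {
  g1 <- generate_multiregion(5, seed = 3)
  g2 <- generate_multiregion(5, seed = 3)
  expect_identical(g1$presence, g2$presence)
  expect_identical(g1$newick, g2$newick)
  # trunk mutations are present in every region
  trunk_lab <- paste(sort(rownames(g1$presence)), collapse = ",")
  trunk_muts <- g1$truth$variant[g1$truth$edge == trunk_lab]
  expect_true(all(g1$presence[, trunk_muts] == 1))
  expect_error(generate_multiregion(9), "n_regions")
})

test_that("expression/methylome generation is deterministic", {
  a <- generate_expression_methylome(20, seed = 6)
  b <- generate_expression_methylome(20, seed = 6)
  expect_identical(a$expression, b$expression)
  expect_identical(a$beta, b$beta)
  expect_true(all(a$beta >= 0 & a$beta <= 1))
})
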