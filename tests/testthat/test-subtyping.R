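test_that("POLE call requires a nonsynonymous exonuclease-domain variant", {
  hit <- make_variants(1, gene = "POLE", protein_change = "p.P286R")
  expect_equal(call_pole(hit)$protein_change, "p.P286R")
  outside <- make_variants(1, gene = "POLE", protein_change = "p.K600N")
  expect_null(call_pole(outside))
  syn <- make_variants(1, gene = "POLE", protein_change = "p.P286P",
                       consequence = "synonymous")
  expect_null(call_pole(syn))
  # hotspot list rescues variants outside the codon interval
  hs <- make_variants(1, gene = "POLE", protein_change = "p.X999Y")
  expect_null(call_pole(hs))
  expect_equal(call_pole(hs, hotspot_list = "X999Y")$protein_change, "p.X999Y")
  expect_warning(call_pole(make_variants(1, gene = "POLE",
                                         protein_change = "garbage")),
                 "unparseable")
})

test_that("MSI-high needs instability at 2 or more of the 6 markers", {
  markers <- c("BAT25", "BAT26", "D2S123", "D5S346", "D17S250", "BAT40")
  panel <- setNames(rep(FALSE, 6), markers)
  panel[c("BAT25", "BAT26")] <- TRUE
  expect_true(call_msi_high(panel))
  one <- setNames(rep(FALSE, 6), markers); one["BAT40"] <- TRUE
  expect_false(call_msi_high(one))
  expect_true(call_msi_high(setNames(rep(TRUE, 6), markers)))
  expect_error(call_msi_high(setNames(rep(TRUE, 5), markers[1:5])), "6 markers")
})

test_that("consensus clustering separates well-separated groups", {
  set.seed(2)
  x <- rbind(matrix(rnorm(10 * 5, 0, 0.1), 10),
             matrix(rnorm(10 * 5, 3, 0.1), 10))
  rownames(x) <- paste0("S", 1:20)
  cc <- consensus_cluster(x, k_range = 2:3, reps = 100, seed = 4)
  cm <- cc$consensus[["2"]]
  within1 <- cm[1:10, 1:10][lower.tri(cm[1:10, 1:10])]
  across <- cm[1:10, 11:20]
  expect_true(all(within1 > 0.99))
  expect_true(all(across < 0.01))
  # duplicated samples always co-cluster
  expect_gte(min(cm[1:10, 1:10]), 0.99)
  # deterministic given seed
  cc2 <- consensus_cluster(x, k_range = 2:3, reps = 100, seed = 4)
  expect_identical(cc$labels, cc2$labels)
  expect_error(consensus_cluster(x[1:3, ], k_range = 2:5), "smaller")
})

test_that("CNH labeling follows cluster burden medians with scalar fallback", {
  counts <- setNames(c(17, 20, 15, 2, 1, 3), paste0("S", 1:6))
  labels <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), paste0("S", 1:6))
  expect_setequal(assign_cnh(labels, counts, min_n = 3), paste0("S", 1:3))
  # all-zero burden: no CNH
  zero <- setNames(rep(0, 6), paste0("S", 1:6))
  expect_length(assign_cnh(labels, zero, min_n = 3), 0)
  # scalar fallback for tiny cohorts
  expect_setequal(assign_cnh(NULL, counts), paste0("S", 1:3))
})

test_that("decision tree order is POLE, then MSI, then CNH, residual CNL", {
  pole_msi <- make_profile("A", make_variants(1, gene = "POLE",
                                              protein_change = "p.P286R"),
                           msi_unstable = c("BAT25", "BAT26", "D2S123"))
  msi_cnh <- make_profile("B", n_aberrant = 30L,
                          msi_unstable = c("BAT25", "BAT26", "D2S123"))
  cnh <- make_profile("C", n_aberrant = 25L)
  cnl <- make_profile("D")
  calls <- classify_cohort(list(pole_msi, msi_cnh, cnh, cnl), reps = 50)
  expect_equal(calls$label, c("POLE", "MSI", "CNH", "CNL"))
  expect_equal(calls$pole_evidence[1], "p.P286R")
  expect_equal(calls$msi_marker_count[2], 3L)
  expect_gte(calls$aberrant_segment_count[3], 8L)
})

test_that("classification fails without an MSI panel", {
  p <- make_profile("A")
  p$msi_panel <- NULL
  expect_error(classify_cohort(list(p)), "MSI panel")
})

test_that("subtype labels are stable under sample-order permutation", {
  profiles <- list(
    make_profile("A", make_variants(1, gene = "POLE", protein_change = "p.P286R")),
    make_profile("B", msi_unstable = c("BAT25", "BAT40")),
    make_profile("C", n_aberrant = 20L),
    make_profile("D")
  )
  c1 <- classify_cohort(profiles, reps = 50)
  c2 <- classify_cohort(profiles[c(3, 1, 4, 2)], reps = 50)
  m <- match(c1$sample_id, c2$sample_id)
  expect_equal(c1$label, c2$label[m])
})

test_that("driver-mutation subtype follows the two-gene-pair rule", {
  endo <- driver_mutation_subtype(make_variants(1, gene = "PTEN",
                                                consequence = "truncating"))
  expect_equal(endo$label, "endometrioid_like")
  sero <- driver_mutation_subtype(make_variants(1, gene = "TP53"))
  expect_equal(sero$label, "serous_like")
  expect_equal(sero$triggering_genes, "TP53")
  none <- driver_mutation_subtype(make_variants(1, gene = "KRAS"))
  expect_equal(none$label, "unclassified")
  expect_length(none$triggering_genes, 0)
  both <- driver_mutation_subtype(rbind(make_variants(1, gene = "ARID1A"),
                                        make_variants(1, pos = 2000L, gene = "TP53")))
  expect_equal(both$label, "endometrioid_like")
  expect_true(both$ambiguous)
  # synonymous variants never trigger
  syn <- driver_mutation_subtype(make_variants(1, gene = "TP53",
                                               consequence = "synonymous"))
  expect_equal(syn$label, "unclassified")
})
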