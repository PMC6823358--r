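caller_set <- function() {
  v1 <- make_variants(3, pos = c(100L, 200L, 300L))
  v2 <- make_variants(2, pos = c(100L, 200L))
  v3 <- make_variants(2, pos = c(100L, 400L))
  list(caller1 = v1, caller2 = v2, caller3 = v3)
}

test_that("consensus merge keeps 2-of-3 supported calls with median VAF/depth", {
  calls <- caller_set()
  calls$caller1$vaf <- c(0.2, 0.3, 0.25)
  calls$caller2$vaf <- c(0.3, 0.32, NA)[1:2]
  calls$caller3$vaf <- c(0.4, 0.5)
  out <- consensus_merge(calls)
  expect_setequal(out$pos, c(100L, 200L))  # 300 and 400 are single-caller
  expect_equal(out$vaf[out$pos == 100L], 0.3)  # median of 0.2/0.3/0.4
  expect_equal(out$callers[out$pos == 100L], "caller1,caller2,caller3")
  expect_equal(out$callers[out$pos == 200L], "caller1,caller2")
})

test_that("consensus merge output is a subset of the input union and idempotent", {
  out <- consensus_merge(caller_set())
  union_keys <- unique(unlist(lapply(caller_set(), variant_key)))
  expect_true(all(variant_key(out) %in% union_keys))
  again <- consensus_merge(list(a = out, b = out, c = out))
  expect_setequal(variant_key(again), variant_key(out))
})

test_that("consensus merge rejects duplicate keys within one caller", {
  bad <- make_variants(2, pos = c(100L, 100L))
  expect_error(consensus_merge(list(c1 = bad, c2 = make_variants(1))),
               "duplicate")
})

test_that("FFPE filters enforce printed boundaries", {
  v <- make_variants(4, pos = c(1L, 2L, 3L, 4L) * 100L)
  v$depth <- c(49, 50, 200, 200)
  v$mapping_quality <- c(60, 60, 29, 30)
  out <- apply_ffpe_filters(v)
  expect_setequal(out$pos, c(200L, 400L))  # depth 50 and MQ 30 retained
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["shallow_depth"]), 1)
  expect_equal(unname(counts["low_mapping_quality"]), 1)
})

test_that("homopolymer-adjacent indels are removed, SNVs are not", {
  hp_ctx <- "CGAAAAACGTACG"   # 5-base run ending at the variant position
  ok_ctx <- "ACGTACGTACGTA"
  v <- rbind(
    make_variants(1, pos = 100L, variant_class = "indel", ref = "AG",
                  alt = "A", context = hp_ctx),
    make_variants(1, pos = 200L, variant_class = "indel", ref = "TG",
                  alt = "T", context = ok_ctx),
    make_variants(1, pos = 300L, context = hp_ctx)  # SNV in a run: retained
  )
  out <- apply_ffpe_filters(v)
  expect_setequal(out$pos, c(200L, 300L))
  v_missing <- make_variants(1, pos = 400L, variant_class = "indel",
                             ref = "AG", alt = "A")
  expect_error(apply_ffpe_filters(v_missing), "context")
})

test_that("cohort-recurrent alleles are removed unless whitelisted", {
  v <- make_variants(2, pos = c(100L, 200L))
  rec <- stats::setNames(c(3L, 1L), variant_key(v))
  out <- apply_ffpe_filters(v, cohort_recurrence = rec)
  expect_equal(out$pos, 200L)
  out_wl <- apply_ffpe_filters(v, cohort_recurrence = rec,
                               whitelist = variant_key(v)[1])
  expect_setequal(out_wl$pos, c(100L, 200L))
})

test_that("variants on aneuploid chromosomes are removed", {
  v <- make_variants(2, pos = c(100L, 200L), chrom = c("1", "2"))
  out <- apply_ffpe_filters(v, chrom_ploidy = c("1" = 3L, "2" = 2L))
  expect_equal(out$chrom, "2")
  # chromosomes without a stated ploidy are treated as diploid
  out2 <- apply_ffpe_filters(v, chrom_ploidy = c("1" = 3L))
  expect_equal(out2$chrom, "2")
})

test_that("chromosome modal ploidy is segment-length weighted", {
  segs <- data.frame(
    sample_id = "S1", chrom = c("1", "1", "2"),
    start = c(1L, 50000001L, 1L), end = c(50000000L, 60000000L, 100000000L),
    log2_ratio = c(0, 0.6, 0.6), integer_cn = c(2L, 3L, 3L)
  )
  pl <- chrom_modal_ploidy(segs)
  expect_equal(unname(pl["1"]), 2L)  # 50 Mb diploid outweighs 10 Mb gain
  expect_equal(unname(pl["2"]), 3L)
})

test_that("FFPE filtering is order-independent across criteria", {
  set.seed(11)
  v <- make_variants(30, pos = seq(100L, by = 37L, length.out = 30))
  v$depth <- sample(c(30, 49, 50, 400), 30, replace = TRUE)
  v$mapping_quality <- sample(c(10, 29, 30, 60), 30, replace = TRUE)
  v$chrom <- sample(c("1", "2"), 30, replace = TRUE)
  rec <- stats::setNames(sample(0:3, 30, replace = TRUE), variant_key(v))
  pl <- c("1" = 2L, "2" = 4L)
  full <- apply_ffpe_filters(v, cohort_recurrence = rec, chrom_ploidy = pl)
  k1 <- variant_key(apply_ffpe_filters(v))
  k2 <- variant_key(apply_ffpe_filters(v, cohort_recurrence = rec))
  k3 <- variant_key(apply_ffpe_filters(v, chrom_ploidy = pl))
  expect_setequal(variant_key(full), Reduce(intersect, list(k1, k2, k3)))
})

test_that("generator-planted artifacts are removed exactly", {
  co <- generate_cohort(cohort_config(n_samples = 12L,
                                      subtype_counts = c(POLE = 1L, MSI = 3L,
                                                         CNH = 6L, CNL = 2L)),
                        seed = 5)
  processed <- process_cohort(co)
  for (i in seq_along(co$profiles)) {
    clean_keys <- variant_key(co$profiles[[i]]$variants)
    got_keys <- variant_key(processed$profiles[[i]]$variants)
    expect_setequal(got_keys, clean_keys)
  }
})

test_that("germline filter keeps only significant nonsynonymous variants", {
  g <- make_variants(4, pos = c(1L, 2L, 3L, 4L) * 50L)
  g$consequence <- c("missense", "synonymous", "missense", "missense")
  g$depth <- c(25, 100, 20, 100)
  g$vaf <- c(0.45, 0.5, 0.5, 0.15)
  g$population_maf <- c(0.001, 0.001, 0.001, 0.001)
  out <- filter_germline(g)
  expect_equal(out$pos, 50L)  # depth 20 fails (> 20 required), vaf 0.15 fails
  g$population_maf[1] <- 0.02
  expect_equal(nrow(filter_germline(g)), 0L)
})

test_that("LOH requires variant read frequency strictly above 0.6", {
  expect_false(call_loh(0.60))
  expect_true(call_loh(0.61))
  expect_false(call_loh(0.50))
})
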