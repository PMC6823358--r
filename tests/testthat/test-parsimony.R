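library(phangorn)

# minimal independent oracle: minimum Fitch parsimony over all unrooted
# topologies, via phangorn
oracle_parsimony <- function(presence) {
  dat <- rbind(presence, germline = 0L)
  pd <- phangorn::phyDat(apply(dat, c(1, 2), as.character), type = "USER",
                         levels = c("0", "1"))
  trees <- phangorn::allTrees(nrow(dat), tip.label = rownames(dat))
  min(vapply(trees, function(t) phangorn::parsimony(t, pd), numeric(1)))
}

test_that("two regions reduce to the trunk/branch partition", {
  keys <- paste0("k", 1:10)
  a <- keys[1:8]; b <- keys[c(1:6, 9, 10)]
  pres <- matrix(0L, 2, 10, dimnames = list(c("Ca", "Sa"), keys))
  pres["Ca", a] <- 1L; pres["Sa", b] <- 1L
  tr <- build_parsimony_tree(pres)
  pt <- partition_trunk_branch(a, b)
  expect_equal(tr$edges$length[tr$edges$is_trunk], unname(pt$counts["trunk"]))
  expect_equal(tr$edges$length[tr$edges$label == "Ca"],
               unname(pt$counts["branch_a"]))
  expect_equal(tr$edges$length[tr$edges$label == "Sa"],
               unname(pt$counts["branch_b"]))
  expect_equal(tr$parsimony_length, 10)
})

test_that("identical regions yield zero-length terminal branches", {
  pres <- matrix(1L, 3, 5, dimnames = list(paste0("T", 1:3), paste0("v", 1:5)))
  tr <- build_parsimony_tree(pres)
  term <- tr$edges[tr$edges$is_terminal & tr$edges$label != tr$outgroup, ]
  expect_true(all(term$length == 0))
  expect_equal(tr$parsimony_length, 5)  # every variant gained once on trunk
})

test_that("perfect-phylogeny characters give length = number of variants", {
  g <- generate_multiregion(n_regions = 5, seed = 12)
  tr <- build_parsimony_tree(g$presence)
  expect_equal(tr$parsimony_length, ncol(g$presence))
  expect_equal(sum(tr$edges$length), tr$parsimony_length)
})

test_that("minimum length matches brute-force enumeration on random instances", {
  set.seed(31)
  for (i in 1:40) {
    m <- sample(3:6, 1)
    nc <- sample(5:30, 1)
    pres <- matrix(rbinom(m * nc, 1, runif(1, 0.2, 0.6)), m, nc,
                   dimnames = list(paste0("T", 1:m), paste0("v", 1:nc)))
    tr <- build_parsimony_tree(pres)
    expect_equal(tr$parsimony_length, oracle_parsimony(pres))
    # edge lengths always sum to the parsimony length
    expect_equal(sum(tr$edges$length), tr$parsimony_length)
  }
})

test_that("more than 8 regions is refused with guidance", {
  pres <- matrix(0L, 9, 3, dimnames = list(paste0("T", 1:9), paste0("v", 1:3)))
  expect_error(build_parsimony_tree(pres), "8 regions")
})

test_that("tree output is deterministic", {
  set.seed(5)
  pres <- matrix(rbinom(4 * 12, 1, 0.5), 4, 12,
                 dimnames = list(paste0("T", 1:4), paste0("v", 1:12)))
  t1 <- build_parsimony_tree(pres)
  t2 <- build_parsimony_tree(pres)
  expect_identical(t1$newick, t2$newick)
})

test_that("planted multi-region topologies are recovered exactly", {
  for (s in 1:8) {
    g <- generate_multiregion(n_regions = sample(3:6, 1), seed = s)
    tr <- build_parsimony_tree(g$presence)
    rf <- ape::dist.topo(ape::unroot(g$phylo), ape::unroot(tr$phylo))
    expect_equal(as.numeric(rf), 0)
    # planted per-edge mutation counts equal recovered edge lengths
    rec <- stats::setNames(tr$edges$length, tr$edges$label)
    for (lab in names(g$edge_counts)) {
      expect_equal(unname(rec[lab]), unname(g$edge_counts[lab]))
    }
  }
})

test_that("drivers are placed on the gaining edge with clonality annotation", {
  # characters force the T1/T2 clade (three supporting characters), so every
  # co-optimal tree contains it; the T1+T3 character is then homoplastic
  pres <- rbind(
    T1 = c(1, 1, 1, 1, 1, 1, 1),
    T2 = c(1, 1, 1, 1, 1, 0, 0),
    T3 = c(1, 1, 0, 0, 0, 0, 1),
    T4 = c(1, 1, 0, 0, 0, 0, 0)
  )
  colnames(pres) <- c("trunk1", "trunk2", "clade12a", "clade12b", "clade12c",
                      "private1", "homo13")
  ccf <- matrix(0.9, 4, 7, dimnames = dimnames(pres))
  ccf["T1", "private1"] <- 0.95
  tr <- place_drivers(build_parsimony_tree(pres),
                      c("trunk1", "clade12a", "private1", "homo13"),
                      ccf = ccf)
  dp <- tr$driver_placements
  expect_equal(dp$edge[dp$driver == "trunk1"], "T1,T2,T3,T4")
  expect_true(dp$on_trunk[dp$driver == "trunk1"])
  expect_equal(dp$edge[dp$driver == "clade12a"], "T1,T2")
  expect_equal(dp$edge[dp$driver == "private1"], "T1")
  expect_true(dp$clonal[dp$driver == "private1"])
  # a mutation shared by T1 and T3 cannot sit on one edge of a tree with the
  # T1/T2 clade: flagged as homoplasy, both gain edges listed
  expect_true(dp$homoplasy[dp$driver == "homo13"])
  expect_setequal(strsplit(dp$edge[dp$driver == "homo13"], ";")[[1]],
                  c("T1", "T3"))
  expect_error(place_drivers(tr, "absent_key"), "absent")
})
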