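archetype_matrix <- function(n_epi = 4, n_mes = 4, noise = 0, seed = 1) {
  set.seed(seed)
  mk <- emt_marker_genes()
  epi <- ifelse(mk$polarity == "epithelial", 3, 0.5)
  mes <- ifelse(mk$polarity == "epithelial", 0.5, 3)
  x <- rbind(
    t(replicate(n_epi, epi + rnorm(nrow(mk), 0, noise))),
    t(replicate(n_mes, mes + rnorm(nrow(mk), 0, noise)))
  )
  dimnames(x) <- list(c(paste0("E", 1:n_epi), paste0("M", 1:n_mes)), mk$gene)
  x
}

test_that("orientation puts mesenchymal archetypes at high scores", {
  x <- archetype_matrix(noise = 0.1)
  sc <- emt_score(x)
  expect_true(min(sc$scores[5:8]) > max(sc$scores[1:4]))
  expect_equal(mean(sc$scores), 0, tolerance = 1e-10)
  expect_gt(sc$variance_explained, 0.5)
})

test_that("duplicated samples get identical scores", {
  x <- archetype_matrix(noise = 0.2)
  x2 <- rbind(x, dup = x[1, ])
  rownames(x2) <- c(rownames(x), "dup")
  sc <- emt_score(x2)
  expect_equal(unname(sc$scores["dup"]), unname(sc$scores[1]))
})

test_that("PC1 projection matches an SVD oracle", {
  x <- archetype_matrix(noise = 0.3, seed = 7)
  sc <- emt_score(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  oracle <- sv$u[, 1] * sv$d[1]
  # comparable up to overall sign
  err <- min(max(abs(sc$scores - oracle)), max(abs(sc$scores + oracle)))
  expect_lt(err, 1e-8)
})

test_that("score differences are invariant to per-gene mean shifts", {
  x <- archetype_matrix(noise = 0.3, seed = 9)
  shifted <- sweep(x, 2, rnorm(ncol(x), 0, 5), "+")
  d1 <- diff(emt_score(x)$scores)
  d2 <- diff(emt_score(shifted)$scores)
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("scoring is robust to gene-order permutation and missing genes", {
  x <- archetype_matrix(noise = 0.2, seed = 3)
  perm <- x[, sample(ncol(x))]
  expect_equal(emt_score(x)$scores, emt_score(perm)$scores, tolerance = 1e-10)
  expect_error(emt_score(x[, -(1:3)]), "missing")
  expect_warning(sc <- emt_score(x[, -(1:3)], allow_subset = TRUE), "subset")
  expect_length(sc$scores, nrow(x))
})

test_that("score tracks planted component content", {
  g <- generate_expression_methylome(60, seed = 5, noise_sd = 0)
  sc <- emt_score(g$expression)
  expect_identical(order(sc$scores), order(g$sarcoma_fraction))
  r <- score_vs_content(sc$scores, g$sarcoma_fraction)
  expect_equal(r$rho, 1)
  # against carcinoma content the correlation flips sign
  r2 <- score_vs_content(sc$scores, 1 - g$sarcoma_fraction)
  expect_equal(r2$rho, -1)
  expect_error(score_vs_content(1:2, 1:2), "at least 3")
})

test_that("top-variance probe selection is deterministic and sane", {
  set.seed(2)
  beta <- cbind(
    flat1 = rep(0.5, 10), var1 = runif(10), var2 = runif(10),
    flat2 = rep(0.2, 10), var3 = runif(10)
  ) + matrix(rnorm(50, 0, 1e-4), 10)
  colnames(beta) <- c("flat1", "var1", "var2", "flat2", "var3")
  sel <- top_variance_probes(beta, fraction = 0.4)
  expect_length(sel, 2)
  expect_true(all(sel %in% c("var1", "var2", "var3")))
  # stable under sample permutation
  expect_identical(sel, top_variance_probes(beta[sample(10), ], fraction = 0.4))
})

test_that("score-coupled probes lead the methylome correlation table", {
  g <- generate_expression_methylome(80, seed = 8)
  sc <- emt_score(g$expression)
  sel <- top_variance_probes(g$beta)
  expect_true(all(g$coupled_probes %in% sel))
  tab <- probe_emt_correlation(g$beta[, sel], sc$scores)
  top_n <- tab$probe[seq_along(g$coupled_probes)]
  expect_gte(mean(g$coupled_probes %in% top_n), 0.9)
  # a probe identical to the score ranks exactly 1
  beta2 <- cbind(g$beta[, sel[1:5]], perfect = rank(sc$scores) / 80)
  tab2 <- probe_emt_correlation(beta2, sc$scores)
  expect_equal(tab2$probe[1], "perfect")
  expect_equal(tab2$rho[1], 1)
})
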