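#!/usr/bin/env Rscript
# Stage 5: EMT scoring of the expression cohort (first principal component
# of the 81-gene marker panel, mesenchymal-high orientation), association
# with component content, and methylome correlation over the top-variance
# probes.

library(csgenomics)

seed <- 20260926L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

g <- generate_expression_methylome(97, seed = seed)
sc <- emt_score(g$expression)
write.table(data.frame(sample_id = names(sc$scores), emt_score = sc$scores,
                       sarcoma_fraction = g$sarcoma_fraction),
            file.path(out, "emt_scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PC1 explains %.1f%% of marker variance\n",
            100 * sc$variance_explained))

assoc <- score_vs_content(sc$scores, g$sarcoma_fraction)
cat(sprintf("EMT score vs sarcoma content: rho = %.4f (p = %.2g, n = %d)\n",
            assoc$rho, assoc$p_value, assoc$n))
assoc_ca <- score_vs_content(sc$scores, 1 - g$sarcoma_fraction)
cat(sprintf("EMT score vs carcinoma content: rho = %.4f\n", assoc_ca$rho))

sel <- top_variance_probes(g$beta, fraction = 0.20)
tab <- probe_emt_correlation(g$beta[, sel], sc$scores)
write.table(tab, file.path(out, "emt_probe_correlation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
n_top <- sum(g$coupled_probes %in% tab$probe[seq_along(g$coupled_probes)])
cat(sprintf("%d/%d planted miR-200-like probes rank in the top correlations\n",
            n_top, length(g$coupled_probes)))
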