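#!/usr/bin/env Rscript
# Stage 1: generate the synthetic carcinosarcoma cohort (109 samples,
# POLE 11 / MSI 24 / CNH 64 / CNL 10) and write its observable tables plus
# the ground-truth record. Later stages regenerate the cohort object from
# the same seed, so the TSVs here are the auditable interchange copy.

library(csgenomics)

seed <- 20260926L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

co <- generate_cohort(cohort_config(), seed = seed)

write.table(co$truth, file.path(out, "cohort_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_variant_tsv(do.call(rbind, lapply(co$profiles, `[[`, "variants")),
                  file.path(out, "cohort_somatic_variants.tsv"))
write_seg(do.call(rbind, lapply(co$profiles, `[[`, "segments")),
          file.path(out, "cohort_segments.tsv"))
msi <- do.call(rbind, lapply(co$profiles, function(p) {
  data.frame(sample_id = p$sample_id, t(p$msi_panel))
}))
write.table(msi, file.path(out, "cohort_msi_panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(co$whitelist, file.path(out, "whitelist_keys.txt"))
write_provenance(file.path(out, "provenance_simulate.yaml"),
                 read_pipeline_config(), seed)

cat("cohort of", nrow(co$truth), "samples;",
    sum(co$truth$repair_pathway != "none"), "planted repair lesions\n")
print(table(co$truth$subtype))
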