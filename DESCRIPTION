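Package: csgenomics
Title: Molecular Subtyping and Clonal Architecture of Gynecologic Carcinosarcoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic-aberration subtyping (POLE-mutated, microsatellite
    instability, copy-number high, copy-number low) of gynecologic
    carcinosarcoma from targeted-panel somatic variant, copy-number and
    microsatellite-marker data; DNA-repair-deficiency annotation (mismatch
    repair, homologous recombination, non-HRD chromosomal instability) from
    germline, somatic, copy-number and promoter-methylation evidence; tumor
    purity from B-allele frequency in LOH regions, cancer cell fractions and
    clonality; maximum-parsimony phylogenies of carcinoma versus sarcoma
    components with driver-timing placement; an epithelial-mesenchymal
    transition score from an 81-gene marker panel together with methylome
    correlation; and a synthetic cohort generator with recorded ground truth
    that emulates the statistical structure of biphasic tumors so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
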