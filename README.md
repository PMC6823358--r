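# csgenomics

Molecular subtyping and clonal-architecture analysis of gynecologic
carcinosarcoma (CS) — a rare, aggressive biphasic tumor with intermixed
carcinoma and sarcoma components — for researchers working with targeted-panel
somatic variant calls, copy-number segments, microsatellite marker panels,
promoter methylation and expression data.

The package implements, as composable and fully tested R functions:

- **Genomic-aberration subtyping** by an ordered decision tree: *POLE*
  (somatic exonuclease-domain mutation, codons 268–471 or hotspot list) →
  *MSI* (instability at ≥ 2 of the 6 markers BAT25, BAT26, D2S123, D5S346,
  D17S250, BAT40) → *CNH* (high-burden cluster under subsampled consensus
  k-means of mean segmented copy number) → *CNL* (residual), plus the 4-gene
  driver-mutation subtype (PTEN/ARID1A → endometrioid-like, TP53/PPP2R1A →
  serous-like).
- **Variant processing**: 2-of-3 caller consensus with median VAF/depth, and
  the five FFPE noise filters (mapping quality < 30, depth < 50,
  homopolymer-adjacent indels, cohort-recurrent non-database alleles,
  aneuploid chromosomes).
- **DNA-repair-deficiency annotation** with one mutually exclusive call per
  tumor: MMR (MLH1 promoter hypermethylation or biallelic MMR-gene lesions),
  HR (BRCA1/RAD51C hypermethylation, germline + LOH in HR genes, somatic
  PTEN), or non-HRD chromosomal instability (CCNE1 amplification, RB1/NF1
  homozygous deletion).
- **Clonality and phylogenetics**: purity from LOH-region B-allele frequency
  (p = 2 − 1/b), cancer cell fractions
  CCF = VAF·(p·n_t + (1−p)·n_n)/(p·m) with standard multiplicity resolution
  and clonality at CCF ≥ 0.8, trunk/branch partitions of carcinoma vs
  sarcoma components, and exact maximum-parsimony trees (exhaustive
  topology search + Fitch counting, ≤ 8 regions) with driver-timing
  placement.
- **EMT scoring**: first principal component of an 81-gene
  epithelial/mesenchymal marker panel, oriented so mesenchymal-like samples
  score high, with top-variance methylome probe correlation.
- **A synthetic cohort generator** (first-class, tested code) that emulates
  the statistical structure of a 109-sample CS cohort — subtype-specific
  burdens and spectra, planted repair lesions at published conditional
  frequencies, biphasic trunk/branch structure, multi-region perfect
  phylogenies, EMT mixing — with every observable derived from a recorded
  ground truth.

## Worked example

The numbered scripts under `analysis/` run the pipeline end to end on a
synthetic cohort (`Rscript analysis/01_simulate.R` … `06_report.R`). The
core loop in code:

```r
library(csgenomics)

co    <- generate_cohort(cohort_config(), seed = 20260926)  # 109 samples
co    <- process_cohort(co)                  # consensus + FFPE filters
calls <- classify_cohort(co$profiles, seed = 20260926)
table(truth = co$truth$subtype, called = calls$label)
```

```
      called
truth  CNH CNL MSI POLE
  CNH   64   0   0    0
  CNL    0  10   0    0
  MSI    0   0  24    0
  POLE   0   0   0   11
```

Every sample lands in its planted subtype: the decision tree inverts the
generator's forward model at panel-like read depth. Repair annotation on the
same cohort recovers 100% of the planted lesions (62 across the cohort:
MMR in 22/24 MSI samples, HR in 23/64 and non-HRD in 17/64 CNH samples):

```r
repair <- annotate_repair_cohort(co$profiles)
table(subtype = co$truth$subtype, pathway = repair$pathway)
```

```
       pathway
subtype HR MMR none nonHRD
   CNH  23   0   24     17
   CNL   0   0   10      0
   MSI   0  22    2      0
   POLE  0   0   11      0
```

Clonal architecture of a biphasic tumor (`analysis/04_phylo.R`): trunk
fractions by subtype show the published pattern — copy-number subtypes share
most mutations between carcinoma and sarcoma, hypermutators branch more —
and the published driver-clonality contrast reproduces exactly:

```
  subtype n_total trunk branch_ca branch_sa trunk_fraction planted_fraction
1    POLE     881   294       306       281         0.3337           0.3500
2     MSI     150    53        54        43         0.3533           0.4500
3     CNH       4     3         0         1         0.7500           0.7568
4     CNL       8     8         0         0         1.0000           0.9375
MSI trunk/branch driver clonality Fisher p: 0.0123
POLE trunk/branch driver clonality Fisher p: 5.4e-06
```

The Fisher p of 0.0123 is the two-sided probability-mass test on the
2/12-branch vs 9/12-trunk clonal-driver table; 5.4e-06 is the 0/26 vs 21/43
table for the POLE subtype. EMT scoring (`analysis/05_emt.R`) tracks the
planted sarcoma content (rho = 0.995 on the default noisy cohort; the sign
flips against carcinoma content), and all 20 planted miR-200-like
methylation probes rank top of the probe–score correlation table.

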