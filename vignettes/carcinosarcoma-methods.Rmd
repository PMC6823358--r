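---
title: "Methods: genomic subtyping and clonal architecture of carcinosarcoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic subtyping and clonal architecture of carcinosarcoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgenomics)
```

Carcinosarcoma (CS) of the uterus and ovary is a biphasic tumor with
intermixed carcinoma (epithelial) and sarcoma (mesenchymal) components.
`csgenomics` implements, as tested and composable functions, an analysis
pipeline for this disease: four-way molecular subtyping from
genomic-aberration profiles, DNA-repair-deficiency annotation, clonal
architecture of the two components (cancer cell fractions, trunk/branch
partitions, maximum-parsimony trees with driver timing), and
epithelial–mesenchymal-transition (EMT) scoring with methylome correlation.
Because the cohorts such analyses are usually run on are access-controlled,
the package ships a first-class synthetic-data generator whose outputs carry
a recorded ground truth; every pipeline stage is validated as a round trip
against that truth.

## Variant processing

Somatic variants enter as per-caller tables keyed on the exact allele
(chrom, pos, ref, alt). A call is accepted when at least 2 of the 3 callers
support it (`consensus_merge`); the VAF and depth of an accepted call are
the medians across its supporting callers. The median rule is our choice —
the convention in consensus pipelines is unstated more often than not — and
it makes the merged VAF insensitive to one outlying caller.

Formalin-fixation noise is removed by five independent criteria
(`apply_ffpe_filters`): mapping quality < 30; read depth < 50 (we read the
inequality strictly, so depth exactly 50 is retained); indels adjacent to a
homopolymer run of ≥ 5 identical bases (a run whose span comes within 1 bp
of the variant position, assessed on a ±6 bp reference-context window);
alleles recurrent in ≥ 2 cohort samples that are absent from a whitelist of
database-recurrent mutations; and variants on aneuploid chromosomes. The
five criteria commute — the result is the intersection of their survivor
sets — and per-criterion removal counts are attached to the result for
audit. "Aneuploid chromosome" has no single established operational
definition; we use a segment-length-weighted modal integer copy number
different from 2 (`chrom_modal_ploidy`), with segment-free chromosomes
treated as diploid.

Germline variants are reduced to the significant set: nonsynonymous, depth
> 20, variant read frequency > 0.2, population minor allele frequency
< 0.01. Pathogenicity is consumed as an input flag; clinical-guideline
interpretation is out of scope. Loss of heterozygosity is called from the
variant read frequency alone, strictly above 0.6 (`call_loh`).

## Subtyping decision tree

`classify_cohort` applies an ordered decision tree. A sample is **POLE**
when it carries a nonsynonymous somatic POLE variant in the exonuclease
domain, taken as codons 268–471 (the standard proofreading-domain
annotation), or a configured hotspot (default P286R, V411L, S297F, A456P,
S459F). Otherwise it is **MSI** when ≥ 2 of the 6 microsatellite markers
(BAT25, BAT26, D2S123, D5S346, D17S250, BAT40) deviate from the matched
normal — a plain count, with no special role for the BAT markers.
Otherwise it is **CNH** when consensus clustering of mean segmented copy
number places it in a high-burden cluster, and **CNL** as the residual
class. The tree order resolves all overlaps (a POLE-mutated MSI-high tumor
is POLE).

Consensus clustering follows the usual subsampled k-means recipe: Euclidean
k-means on 80% row subsamples, 1000 iterations, consensus matrix = fraction
of co-clustering among co-drawn pairs. The number of clusters is selected
from the consensus-CDF area: we take the largest k whose relative area gain
is still at least 0.05. This is the practical reading of the area-change
criterion; taking the single largest change would nearly always return
k = 2, which merges the copy-number-low samples into the low end of the
high-burden group. Labels come from average-linkage hierarchical clustering
of the chosen consensus matrix, so the procedure is deterministic given its
seed.

"Resembles the high-copy-number reference cluster" is a visual criterion,
not a computable one, so CNH labeling is burden-ranked (`assign_cnh`): a cluster
is CNH when its median count of aberrant segments (|log2R| ≥ 0.3, a
configurable threshold) reaches the scalar threshold 8, or exceeds the
cohort median by a margin (default 4). Cohorts too small to cluster fall
back to the per-sample scalar rule. All three constants are config
parameters; 8 sits between the observed CNL-like (median ≈ 2) and CNH-like
(median ≈ 17) burden regimes.

The driver-mutation subtype is a two-rule classifier evaluated in order:
PTEN or ARID1A mutation → endometrioid-like; else TP53 or PPP2R1A →
serous-like; else unclassified. Samples matching both gene pairs are
endometrioid-like and flagged ambiguous.

## Repair-deficiency annotation

`annotate_repair_cohort` assigns each tumor exactly one mechanism. Promoter
hypermethylation is called on probes selected cohort-wide per gene (range
> 0.4 and median < 0.1 across samples — probes silent in most tumors but
strongly methylated in some), with a per-sample mean β cutoff of 0.4. We
treat the cutoff as inclusive (≥ 0.4): the direction at equality is not
stated in our sources, and an inclusive boundary keeps the call monotone in
β with no surprises at equality. Copy-number classes are amplification
(CN ≥ 6), gain (3–5), neutral (2), loss (1), homozygous deletion (0).

MMR deficiency requires MLH1 hypermethylation, or a germline pathogenic /
somatic truncating lesion in MLH1, MSH2, MSH6 or PMS2 with biallelic
evidence (LOH of the variant, or a second somatic hit in the same gene);
the biallelic requirement for somatic single hits is a config flag because
single-hit calling is a defensible alternative. HR deficiency requires
BRCA1/RAD51C hypermethylation, germline inactivation plus LOH in BRCA1/2,
ATM, RAD50, BLM or RAD51C, or — as the weakest evidence — a nonsynonymous
somatic PTEN mutation. Non-HRD chromosomal instability is CCNE1
amplification or RB1/NF1 homozygous deletion. Mechanisms co-occur
occasionally; precedence MMR > HR > nonHRD, and within a pathway
hypermethylation > germline+LOH > somatic, yields a single call, with the
displaced mechanisms recorded in a `co_occurring` column rather than
discarded.

## Purity, CCF and clonality

Tumor purity comes from the B-allele frequency of the major allele in LOH
regions. Under single-copy loss a tumor of purity $p$ mixed with diploid
normal gives $b = 1/(2-p)$, hence $p = 2 - 1/b$; a copy-neutral-LOH variant
of the model ($p = 2b - 1$) is available by argument. The estimate is the
median across regions, clipped to (0, 1]; $b \le 0.5$ carries no signal and
is an error.

The cancer cell fraction of a variant is
$\mathrm{CCF} = v\,(p\,n_t + (1-p)\,n_n)\,/\,(p\,m)$ with VAF $v$, local
tumor/normal copy numbers $n_t, n_n$ and multiplicity $m$. When $m$ is not
supplied it is resolved as the value in $1..n_t$ minimizing
$|\mathrm{CCF}-1|$ among candidates with $\mathrm{CCF} \le 1.2$, the
standard practice; when no candidate satisfies the cap the largest
multiplicity is used. A mutation is clonal when CCF ≥ 0.8; both exclusive
and inclusive readings of that boundary circulate, and we adopt the
inclusive one, so the boundary value 0.80 is clonal.

## Trees

For two components the trunk/branch partition is exact set algebra on
variant keys. For multi-region samples `build_parsimony_tree` performs an
exhaustive search over all unrooted binary topologies on the regions plus
an all-absent germline outgroup — up to 8 regions, i.e. 9 leaves and
135,135 topologies; more regions are refused rather than silently
approximated. Each topology is scored by Fitch small parsimony on the
binary presence/absence characters; rooting on the outgroup edge keeps
every internal node binary, so the textbook two-pass algorithm applies
unchanged. Among equally parsimonious trees we return the one with the
lexicographically smallest sorted clade signature, making the output
deterministic; ties are common on conflicting characters and a silent
arbitrary choice would make runs irreproducible. Edge lengths are the
number of character changes assigned by the deterministic top-down
refinement with the root fixed to the germline state; they always sum to
the parsimony length. Characters missing in a region are treated as absent.
Drivers are placed on the edges where their absent→present change occurs;
a driver with several gain edges is homoplastic and flagged with all its
gain edges rather than forced onto one.

## EMT score and methylome correlation

The EMT score is the projection of each sample on the first principal
component of the 81-marker-gene expression matrix (log10(FPKM+1) scale),
columns centered but not scaled — log expression is already comparable
across genes, and unit-variance scaling is available by flag. The sign of a
principal component is arbitrary, so the component is oriented by the
marker polarity map: mesenchymal markers must load positively, making
sarcoma-like samples score high. The 81-gene panel shipped in
`inst/extdata/emt_markers_synthetic.tsv` is a curated stand-in of canonical
epithelial/mesenchymal markers (the original panel is not reprinted in our
sources); the scoring machinery is list-agnostic and the fixture is
editable. Methylome correlation restricts to the top 20% most variable
probes (ties broken by probe id) and reports per-probe Spearman rho,
descriptively and unadjusted.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
sequencing data. Its defaults are the study conditions: 109 samples split
POLE 11 / MSI 24 / CNH 64 / CNL 10 (the CNL count is the remainder of the
cohort after the three published counts); per-subtype burden counts drawn
from two-piece log-uniform distributions anchored at published range and
median (e.g. POLE SNVs 190–1999, median 479; MSI indels 10–63, median 27;
CNH copy-number events median 17). The two-piece construction — half the
mass log-uniform on [min, median], half on [median, max] — has exactly the
printed median, which we prefer over rejection-adjusting an ordinary
log-uniform: same anchors, no accept/reject loop. CNL burdens are not
printed anywhere; we chose SNV 1–30 (median 8), indel 0–5 (median 1), CNV
0–7 (median 2), below the hypermutator and CNH anchors on the respective
axes. Substitution spectra elevate T>C in MSI and T>G in POLE.

Two generator choices depart from a literal reading of the published
marginal ranges, both for identifiability and both confined to the
copy-number axis. First, CNH CNV counts are drawn from 9–48 (median 17)
rather than 1–48: a high-burden tumor with a single aberrant segment is
indistinguishable from a low-burden tumor by any burden-based rule, and the
planted labels would be unrecoverable by construction. Second, CNH samples
accumulate their aberrations over a fixed 16-arm signature in a fixed
recurrence order (gains on chromosomes 1–8, losses on 9–16, most recurrent
first), emulating the strongly recurrent arm-level changes of
copy-number-driven gynecologic tumors; the remainder and all non-CNH
aberrations fall on random arms. This gives the consensus clustering an
actual shared profile to find rather than i.i.d. noise.

Reads are simulated forward through the mixture model: a variant with
planted CCF, purity $p$ and multiplicity $m$ has expected VAF
$\mathrm{CCF}\cdot p\,m/(p\,n_t+(1-p)\,n_n)$, and observed counts are
binomial at Poisson-drawn depth around 300 (panel-like coverage). Purity is
uniform on 0.3–0.9 (samples below 0.3 purity are excluded from such
studies). LOH-region BAFs are binomial with an effective allele-count depth
of 2000 per region over 8 regions: a region-level BAF aggregates reads
across many heterozygous sites, and at these settings the purity estimator
stays within 0.05 of truth across a cohort. Repair lesions are planted
deterministically at the published conditional frequencies (MMR in 22/24
MSI samples; HR in 23/64 and non-HRD in 17/64 CNH samples, the latter split
15 CCNE1 amplifications to 2 RB1 deletions), one mechanism per sample, at
fixed catalog positions that double as the database-recurrence whitelist.
Each per-caller table carries the clean calls (drivers always by all 3
callers, passengers by 3 or a random pair), planted filter-target artifacts
supported by exactly 2 callers, and single-caller noise — so consensus and
filtering are both exercised nontrivially.

What the generator does **not** emulate: real sequence context (the
"genome" is a deterministic 4-base cycle over synthetic coordinates),
caller-specific error profiles, subclonal copy-number, tumor-in-normal
contamination, or correlated passenger landscapes. Passing round-trip tests
therefore demonstrates that the pipeline inverts its own generative
assumptions at realistic noise — not that it is robust to everything real
FFPE panel data can do.

Biphasic tumors are generated by Bernoulli-sharing each mutation with the
subtype's trunk-fraction probability (defaults: CNL 15/16, CNH 56/74,
POLE 0.35, MSI 0.45 — the hypermutator values are our choice of "shorter
trunks, longer branches"); the recorded truth keeps both the planted
probability and the realized fraction, and the partition recovers the
realized fraction exactly. Multi-region tumors drop Poisson mutation counts
on the edges of a random bifurcating topology (internal edges and trunk
carry at least one mutation so the topology is identifiable); with zero
homoplasy the presence matrix is a perfect phylogeny and reconstruction
must return Robinson–Foulds distance 0. Expression/methylome cohorts mix
epithelial and mesenchymal archetypes by a planted sarcoma fraction, with
20 of 500 β-probes linearly coupled to the fraction (the miR-200-promoter
analogue).

## Problem sizes and determinism

The validation suite runs cohorts of n = 109 over 10 seeds for subtype
recovery, 3 cohorts for repair and purity recovery, 500 random parsimony
instances at 3–6 regions and up to 30 characters against independent
brute-force enumeration, 80 biphasic simulations and 97-sample expression
cohorts — sizes chosen so the full suite completes in a few minutes while
keeping every estimate's sampling error well inside its acceptance margin.
All randomness flows through explicit integer seeds; every generator and
the consensus clustering restore the caller's RNG state.

## Known limitations

The CNH/CNL boundary is only as good as the aberrant-segment threshold and
the clustering; tumors with genuinely intermediate burden have no defined
truth. The homopolymer filter sees only the ±6 bp shipped context, not a
genome. Exhaustive parsimony is exact but exponential; 9+ regions need an
external heuristic search. The purity model assumes a single LOH mechanism
per region and no subclonal copy number. The EMT orientation rule requires
both polarities present among markers. None of the survival analyses of the
source study are implemented (routine Cox/log-rank machinery is available
in the `survival` package and was deliberately left out of scope).
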