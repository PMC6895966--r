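---
title: "Methods: somatic filtering and paired VAF dynamics in mutdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic filtering and paired VAF dynamics in mutdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutdyn)
```

# Scope

`mutdyn` analyzes targeted-panel somatic variant calls from paired pre- and
post-neoadjuvant-chemotherapy tumor samples: FFPE-aware filtering,
mutational-landscape summaries, gene/pathway association with pathological
complete response (pCR), per-patient clonal dynamics from paired variant
allele frequencies (VAFs), and co-occurrence/network/enrichment analysis.
This vignette records the models, the tunable parameters, and the numerical
and design choices, so that every default is traceable.

# The filter cascade

The eight rules and their thresholds (see `filter_thresholds()`) encode
standard evidence requirements for FFPE panel data. Thresholds are plain
numbers in the units of the evidence fields: phred quality (R1, minimum 30),
strand-bias p-value (R2, minimum 0.01), variant-supporting reads (R3,
minimum 7), VAF as a fraction with a depth rescue (R4: fails only below 5%
VAF *and* below 500x depth — deep coverage makes a low fraction credible),
the FFPE deamination gate (R5: C>T/G>A below 10% VAF), population allele
frequency 1% with corroborating evidence (R6), and normal-sample depth and
VAF gates (R7: 10x, R8: 10%).

Numerical conventions:

* Comparisons are exactly as written: a VAF of exactly 0.05 **passes** R4,
  a depth of exactly 500 escapes R4's depth clause, a normal VAF of exactly
  0.10 **fails** R8. Boundary behavior is pinned by tests.
* All eight rules are evaluated for every variant — no short-circuiting —
  so the audit trail (`failed_rules`, `skipped_rules`) is complete. R7
  logically subsumes R6's shallow-normal clause; both are still evaluated
  and recorded separately, favoring audit fidelity over minimality.
* Missing evidence: a rule whose required field is missing is *skipped* and
  flagged in lenient mode (the default — plain MAF input lacks the extended
  evidence columns), or discards the variant in strict mode. Missing
  population frequencies count as 0 for R6: absence of evidence that an
  allele is common. Logical connectives use three-valued logic, so a rule
  settled by its present operands (e.g. a rare allele settles R6 to
  "does not fire" whatever the dbSNP field) counts as evaluated.
* R6's sentence structure is genuinely ambiguous. The default parse is
  `pop_af >= 1% AND (dbSNP OR normal_depth < 10x)`: a population-frequency
  filter should fire only on common alleles; the alternative left-to-right
  parse (`dbSNP OR (shallow normal AND common)`) would discard every dbSNP
  variant regardless of frequency, including rare pathogenic entries. Both
  parses are implemented (`r6_parse`).

Impact tiers follow the standard controlled vocabulary: HIGH groups the
truncating / loss-of-function classes, MODERATE the protein-altering
non-truncating ones, LOW is silent, MODIFIER everything else. Downstream
analyses (burden's primary count, onco-matrix, binarization) use
HIGH/MODERATE, with an all-mutations count kept alongside for burden.

# Exact statistics

All inferential machinery routes through five small functions
(`fisher_exact_2x2()`, `hypergeometric_upper_tail()`, `bh_fdr()`,
`wilcoxon_rank_sum()`, `wilcoxon_signed_rank()`), thin validated wrappers
over the corresponding base R routines, which implement exactly the
conventions required here:

* Two-sided Fisher p-values use the *point-probability* definition — the
  sum of hypergeometric probabilities of all tables (margins fixed) no more
  probable than the observed one — with a relative comparison tolerance of
  1e-7 so boundary tables classify identically across platforms. The
  reported odds ratio is the sample cross-product `(a d)/(b c)` (infinite
  when `b c = 0` with `a d > 0`, undefined when both vanish), not the
  conditional MLE.
* The hypergeometric upper tail is computed in log space (`phyper`), never
  by naive summation.
* Rank tests take the exact enumeration path for small untied samples
  (rank-sum: smaller group at most 25 — cohorts here are far below that;
  signed-rank: at most 15 effective pairs after dropping zero differences)
  and the mid-rank normal approximation with continuity correction
  otherwise. The test suite checks all of them against independent
  brute-force enumeration oracles on hundreds of random instances.

Exact conditional tests are discrete and conservative: under label
permutation their rejection rate at nominal 5% falls below 5% rather than
matching it. The null-calibration suite therefore asserts one-sided type-I
control (and FDR control for the co-occurrence scan), not two-sided
calibration around the nominal level.

# Paired VAF clustering and profile calls

Each paired patient's mutations, keyed by genomic identity
`chromosome:position:ref>alt` (never by gene symbol — two different
mutations of one gene must not be conflated as shared), become points in
the (pre-VAF, post-VAF) plane; a mutation undetected at a timepoint enters
as 0 rather than being dropped, because loss and emergence are the signal
of interest. Raw VAFs are used, unscaled.

Clustering is agglomerative with Ward's minimum-variance criterion on
Euclidean distances (`hclust(method = "ward.D2")`, verified against an
exhaustive minimum-variance-increase agglomeration oracle for n <= 8). The
number of clusters maximizes mean silhouette width over
k = 2..min(6, n-1); rows are processed in lexicographic key order, ties in
the silhouette resolve to the smaller k, and clusters are relabelled
C1..Ck by decreasing mean pre-treatment VAF — all deterministic. When fewer
than 4 mutations are available, or the best silhouette falls below 0.25, a
single cluster is used.

Fates use a detection threshold of 0.05 — deliberately the same value as
the filter's VAF floor (R4), for internal consistency: a cluster is *lost*
when every member is below threshold after treatment and at least one was
detectable before, *emergent* in the mirror case, *retained* otherwise. A
patient is *changed* when any cluster was lost or emerged.

One deliberate refinement of the profile rule: when only a single cluster
is resolved (k = 1), the profile call falls back to per-mutation fates
(`small_n_profile = "mutation"`, the default). With the strict
cluster-level rule, a two-mutation patient with one retained clonal
mutation and one clearly lost mutation averages into a single "retained"
cluster and is structurally un-callable as changed; judged at the mutation
level, a unique mutation present at both timepoints is a stable profile and
one that vanished is not — which is also how such patients are judged in
practice. Setting `small_n_profile = "cluster"` restores the strict rule.
The mutation fallback applies *only* at k = 1; multi-cluster patients are
always judged by cluster fates.

Known limitation: silhouette width is 0 for singleton clusters, so when a
lost or emergent clone carries only one or two mutations and sits near a
retained subclone, k is occasionally underestimated and the patient
miscalled stable. On simulated 50-patient residual-disease cohorts the
planted-profile recovery of the full pipeline is about 0.82–0.98 depending
on the realization (0.98 at the fixed validation conditions used in the
acceptance suite); the residual errors trace to exactly this singleton
effect plus filter-boundary flicker of C>T mutations near 10% VAF.

# The synthetic cohort generator

`simulate_cohort()` exists because per-patient variant data for this study
design are typically not deposited; it provides ground truth for every
pipeline stage. What it emulates, per patient:

* **Clonal structure.** 1–4 clones with cancer-cell fractions (CCFs) from a
  stick-breaking draw rescaled so the largest clone is clonal (CCF 1).
  Expected VAF is `purity * CCF / 2` — a diploid, heterozygous,
  copy-number-neutral model, the simplest identifiable one (the default
  purity 0.6 is a typical macrodissected-FFPE figure and is configurable).
* **Treatment effect.** Residual-disease patients are *changed* with
  probability 8/12 (the observed proportion in cohorts of this design):
  one planted clone with CCF 0.4–0.9 on one side and 0 on the other (lost
  or emergent, 50/50), other clones jittered within ±0.025 (stable
  contract: every clone moves at most 0.05). A changed patient always has
  at least two mutations and two clones, so the planted clone genuinely
  exists; if clone ranges make planting impossible the truth label reverts
  to stable. pCR patients have no post-treatment sample at all (no residual
  tumor to sequence).
* **Counts and noise.** Per-patient mutation counts are
  `1 + NB(size 0.9, mu 7)` clamped to 1–66, calibrated once so that the
  *observed* per-sample burden — after read sampling and filtering,
  high/moderate impact — has median about 4 with a long upper tail. Depth
  is a shifted negative binomial (mean 800, size 8, support from 1);
  alternate reads are binomial in the true VAF. A variant row is emitted at
  a timepoint only when at least one alternate read is sampled.
* **Contaminants.** Poisson numbers of FFPE artifacts per sample (rate 3):
  C>T or G>A SNVs with true VAF uniform on (0.01, 0.09); and germline
  leak-throughs (rate 2): normal VAF uniform on (0.35, 0.65) — all
  removable by R8 by construction — with population AF >= 1% with
  probability 0.8 and dbSNP membership with probability 0.9.
* **Clinical labels.** TP53 planted as a clonal mutation with probability
  0.87 per patient; relapse probability 1 for stable-profile patients,
  0.375 for changed, 0 for pCR; ages, stages, grades and stromal TIL
  percentages drawn from plausible ranges as inert covariates.

Determinism: one global seed; per-patient (and per-sample, for injection)
substreams derive from it by fixed integer offsets, so cohorts are
bit-reproducible and stable under patient subsetting.

What it does **not** emulate — and therefore what passing tests do not show
about real data: copy-number alterations and their VAF distortion, subclonal
phylogenies, panel footprint (the gene pool is a representative ~130-symbol
cancer-gene list, not any specific commercial panel), a biologically biased
substitution spectrum (true somatic substitutions are sampled uniformly
over the six classes, so the C>T/G>A dominance of real FFPE breast tumors
appears only via injected artifacts), sequencing-error base noise,
spatial heterogeneity of multi-region biopsies, and the mostly-subclonal
private mutations that real paired samples show near the detection limit.

# Association, co-occurrence, enrichment

Only pre-treatment samples enter the response association: post-treatment
samples exist only for residual-disease patients, so including them would
confound timepoint with response perfectly. FDR is computed within scope —
genes separately from pathways — and, in enrichment, within source (KEGG
pathways gated at q < 0.05, GO terms at q < 0.01, both configurable).
Features mutated in no or all samples carry no 2x2 information and are
reported with p = 1 and an `informative = FALSE` flag rather than dropped.
The reporting filter for non-responder-enriched pathways (mutated in at
least 3 RD samples and no pCR sample) exposes both counts as parameters.

The co-occurrence scan tests all pairs of genes mutated in at least 2
samples; the significance gate defaults to BH FDR < 0.05 (a raw-p gate is
available, since both conventions circulate). Mutual-exclusivity pairs are
computed but excluded from module seeding by default. Pair tables are
formed by matrix cross-products and one exact test is computed per distinct
table, which keeps 500-replicate null calibrations cheap; the vectorized
path is oracle-checked against per-pair tests.

The interaction module is the seeds plus their first neighbors, with edges
restricted to that node set; disconnected components are retained and
labelled by decreasing size. The enrichment universe is a required explicit
argument — conventions differ (panel genes, gene-set vocabulary, PPI node
set), and silent defaults are the commonest source of inflated enrichment.

# Problem sizes in the validation suite

The shipped tests run at sizes chosen for thorough coverage at interactive
cost: oracle equivalence on 200–1000 random instances per statistic, filter
oracle on 1000 random variants with all eight thresholds pinned at their
boundary values, Ward-oracle comparison for n <= 8, planted two-cluster
recovery at separation >= 0.3 and noise sigma 0.02, cohort recovery on 50
simulated patients, and null calibration with 500 label permutations
(association) and 500 null matrices of 40 genes by 50 samples
(co-occurrence FDR). The full suite runs in a few minutes on one CPU.
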