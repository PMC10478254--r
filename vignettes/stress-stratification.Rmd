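---
title: "Stratifying cohorts by stress-responsive gene expression"
author: "stressStrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying cohorts by stress-responsive gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressStrat)
```

## The problem

Psychiatric case series are heterogeneous: some patients' molecular
profiles suggest a strong imprint of environmental stress (elevated
inflammatory cytokines and antioxidant enzymes, depleted synaptic and
neurotrophic markers), others' do not. stressStrat implements a complete,
reproducible pipeline for splitting a bulk RNA-seq cohort into high (HSR)
and low (LSR) stress-response subgroups from a configurable panel of
stress-responsive genes, and for the analyses that hang off that split:
subgroup contrasts, differential expression with gene-set
overrepresentation, an index-based classification of control subjects,
and TUNEL histology quantification.

Because the postmortem datasets this style of analysis targets are
typically access-restricted, the package treats synthetic data as a
first-class citizen: `simulateCohort()` and `renderField()` generate
cohorts and stained tissue fields with known ground truth, and the test
suite exercises every stage against that truth.

## Stratification model

The panel (default: `defaultStressPanel()`, 19 genes) carries each gene's
expected direction under stress: UP (IL1B, IL6, IFNG, TNF, SOD1–3), DOWN
(BDNF, IL10, DLG4/PSD95, SYP, SNCA, SNCB, SNCG), or VARIABLE (APOA1,
APOA2, NR3C1/GR, S100B, SLC6A4), the latter for genes whose reported
direction is inconsistent across studies. Panel genes are matched against
the matrix case-insensitively with protein-name aliases, since expression
tables mix gene and protein symbols.

Each panel gene is z-scored across samples (sample sd, n−1 denominator;
a zero-variance gene is an error, not a silent drop). Samples are then
clustered with Ward's minimum-variance criterion on squared Euclidean
distances over the z-scores — the standard precondition for Ward linkage
and the convention of the SPSS implementation whose dendrograms this
reproduces. Our `wardCluster()` maintains the merge cost

ΔSSE(i, j) = nᵢnⱼ/(nᵢ+nⱼ) · ‖cᵢ − cⱼ‖²

via the Lance–Williams recurrence, and records ΔSSE as the merge height.
Ties in the minimal cost are broken by the lexicographically smallest
(smallest-leaf, smallest-leaf) pair so results are identical across
platforms. The test suite checks the implementation against a brute-force
agglomerator that recomputes ΔSSE from the raw points at every step, and
against `stats::hclust(method = "ward.D")` (whose heights are exactly
2·ΔSSE on squared distances).

### The rescaled-distance cut

Merge heights are mapped to the familiar 0–25 dendrogram axis by
h′ = 25·h/h_max, and all merges with h′ at or below the threshold
(default 20) are applied; the inclusive boundary means a cut at 25 always
yields a single cluster, and Ward's monotone heights make the applied
merges a prefix of the schedule. Whether the plotted axis derives from
incremental ΔSSE heights or the cumulative agglomeration coefficient is
not standardized across software; both are available
(`schedule = "incremental"` (default) or `"cumulative"`), and with the
strong subgroup structure the pipeline targets the two agree on the
2-cluster cut.

### Labeling

With exactly two clusters, each cluster's *directional concordance* is
the mean z over UP genes minus the mean z over DOWN genes; the
higher-concordance cluster — more of what stress raises, less of what
stress suppresses — is HSR. VARIABLE genes contribute to the clustering
features but not to labeling, because only direction-consistent genes
carry a sign. An exact concordance tie raises an error rather than making
a silent choice.

## The stress-response index for controls

Controls are classified without re-clustering: for each gene of the index
panel (default `defaultIndexPanel()`: IL6, IFNG, SOD2, NR3C1, APOA1,
SLC6A4 higher-in-HSR; BDNF, SYP, DLG4, SNCA higher-in-LSR), subjects are
assigned quartiles computed *within the classified subset only*, and
quartiles 1–4 score (−3, −1, 1, 3) or (3, 1, −1, −3) according to the
gene's direction. The index is the sum; positive ⇒ HSR, negative ⇒ LSR.

Numerical choices the scoring rule itself does not pin down:

- Quartile cut points use `stats::quantile(type = 8)` (linear
  interpolation, median-unbiased), so the rule depends only on values —
  with 21 controls the quartile groups are necessarily unequal, and
  rank-splitting would depend on tie order.
- Membership intervals are closed on the right (v ≤ Q1 ⇒ quartile 1), a
  deterministic convention for values equal to a cut point.
- A score of exactly 0 satisfies neither strict inequality; such subjects
  are reported as INDETERMINATE (with a warning) and excluded from
  downstream contrasts rather than silently binned. In simulated 14/7
  control cohorts about 5% of subjects land there; recovery metrics are
  therefore computed over classified subjects.

## Differential expression and overrepresentation

Per-gene two-sided pooled-variance Student t-statistics are computed on
log2(CPM+1); the pseudocount-log transform stabilizes variance for
low-expression genes, and which scale the t-test should use is exposed by
construction (the input matrix) rather than hidden. Genes with zero
variance in both groups are excluded with a reported count. The top-N
list (ties broken by |t|, then gene id — deterministic under any input
order) feeds a right-tailed hypergeometric overrepresentation test per
gene set, with BH q-values across sets; the universe defaults to all
genes surviving the variance filter, since the reference set of a
proprietary pathway tool cannot be known. Each overlapping gene is
annotated with the sign of its fold change, supporting
elevated/suppressed summaries of a hit pathway.

## Exact statistics

`mannWhitneyU()` enumerates all rank splits when n₁+n₂ ≤ 12 without ties
(two-sided p = 2·min tail, capped at 1) and otherwise uses the normal
approximation with tie and continuity corrections, reporting the effect
size r = |Z|/√N on that path. `fisherExact2x2()` and `fisherExactRxC()`
sum the (multivariate) hypergeometric probabilities of all tables with
the observed margins that are no more probable than the observed table —
the minimum-likelihood two-sided rule used by mainstream software. The
R×C enumeration is exact up to a configurable grand total (default 60;
beyond that the error message points at a Monte-Carlo strategy, which is
deliberately out of scope). Every exact path is tested against an
independent brute-force oracle and against the corresponding `stats::`
function.

## The synthetic cohort generator

`simulateCohort()` encodes the study conditions the pipeline assumes:

- 25 cases in latent subgroups of 7 (HSR) and 18 (LSR), and 21 controls
  in latent subgroups of 14 and 7.
- Panel-gene subgroup means in CPM from the reported group contrasts
  (e.g. IL6 0.77 vs 0.38; SOD2 84.7 vs 46.1; SYP 350.1 vs 556.3; BDNF
  0.30 vs 0.51). Control subgroups use the reported control means where
  printed; otherwise midpoint ± 0.8 × the case half-difference — 0.8 is
  the typical ratio of control to case separations across the genes for
  which both are printed. Index genes without printed means (NR3C1,
  APOA1, SLC6A4, and IFNG beyond the case table) are given plausible CPM
  levels with a subgroup difference, since the index panel was chosen
  for genes showing between-group differences; panel genes outside the
  index with no reported contrast are kept flat across groups.
- Counts are negative binomial with dispersion φ = 0.1 (variance
  μ + φμ²) at a simulated library size of 46.6 million reads (CV 0.15),
  then rescaled to CPM. φ = 0.1 reproduces the coefficient of variation
  implied by the reported group SEMs (≈0.33 for a moderately expressed
  gene) and is a standard bulk-brain overdispersion; φ = 0 falls back to
  Poisson.
- 2000 background genes with log-normal mean CPMs (meanlog log 20,
  sdlog 1.5) shared across groups, except a planted set (default 7
  genes, log2FC 1 in latent HSR cases) that stands in for a stress-linked
  pathway; decoy sets for enrichment testing are drawn from the
  unshifted background.
- Clinical covariates (age, sex, RIN, PMI, antipsychotic dose, family
  history, cause-of-death category) echo the cohort's demographic tables
  so the Fisher/Mann–Whitney plumbing runs on realistic input; they do
  not feed back into expression.

What the generator does **not** emulate: RIN- or PMI-dependent expression
gradients, agonal-state effects, gene–gene correlation beyond the group
structure, and compositional coupling between panel and background genes.
Passing recovery tests therefore demonstrates that the pipeline's
machinery is correct and well-calibrated for group-structured
overdispersed data — not that real cohorts will separate this cleanly.

## Histology rendering and quantification

`renderField()` composes 512×512 two-stain fields by the Beer–Lambert
law: each non-overlapping disk (radius 30–36 px by default, echoing
nuclei at ×40 that pass a 2000 px² filter) carries DAB (amplitude 0.8)
or methyl green (0.7); transmitted intensity is
I_c = 255·10^(−OD_c) per channel, plus Gaussian noise (sd 2 gray levels)
and 8-bit quantization. Disks are kept disjoint because the particle
counter deliberately has no declumping stage. The DAB optical-density
vector is the widely published brightfield triplet (0.268, 0.570, 0.776);
methyl green has no canonical published vector, so the shipped
(0.620, 0.200, 0.760) was estimated once from a pure-stain synthetic
fixture and both are user-overridable.

`quantifyField()` inverts that composition: per-pixel OD
(−log10(max(I,1)/255)) through the inverse stain matrix (a residual
cross-product vector completes a 2-stain basis), negative concentrations
clipped; the isodata fixed point t = (mean(≤t)+mean(>t))/2 binarizes each
channel (the plain intermeans fixed point — ImageJ's "Default" variant is
a close but not identical histogram-based relative, a documented possible
minor divergence); 8-connected particles are filtered by area ≥ 2000 px²
and circularity 0.1–1. Perimeter is measured by tracing the outer
boundary with unit axial and √2 diagonal steps; under this rule a 50×50
square measures 196 (so circularity ≈ 0.82) and rasterized disks of
radius ≥ 15 stay above 0.9, comfortably clear of the 0.1 lower bound —
the filter pair rejects a 20 px-radius disk (area 1257) and keeps a 30 px
one (area 2821). Case-level positivity pools counts over fields rather
than averaging per-field rates, so sparse fields do not dominate; whether
TUNEL-positive nuclei should also be counted in the denominator via the
counterstain channel is not settled, and the pooled-two-channel
denominator is one documented reading. Images are indexed (row, column)
from the top-left, 1-based, the R convention.

## Pipeline arms, determinism and problem sizes

`runSZArm()` chains standardize → cluster → cut(20) → label → panel-gene
Mann–Whitney contrasts (+ Fisher tests on cause-of-death and
family-history tables when metadata provides them) → DEG → top-N → ORA;
`runControlArm()` mirrors it with the index in place of clustering, and
can add the four-group contrast table (HSR/LSR × case/control per gene).
Errors carry their stage name. All outputs are written with fixed
formatting and no timestamps, and every stochastic step takes an explicit
seed, so a rerun with the same inputs is byte-identical — the run
manifest (config, seed, stage counts) suffices to reproduce a run.

The test suite and the acceptance script run at deliberately compact
problem sizes chosen to exercise the full pipeline: cohorts of 25 + 21
samples with 19 panel and up to 2000 background genes; a 200-gene DEG
list over the 2000-gene universe for enrichment (the same ~10% list
fraction a genome-scale 8000-of-80k selection would give, keeping the
planted-set hypergeometric signal realistic); 100 rendered fields of
~20 cells for count-recovery; 10,000 null replicates for type-I
calibration; exact-test oracle sweeps over all 2×2 tables with margins
≤ 10.

## Known limitations

- Ward heights are exact ΔSSE increments; software that plots cumulative
  coefficients will show the same topology with differently scaled axes.
- The R×C exact test is enumeration-only (total ≤ 60 by default).
- The quartile index is sensitive to the subject subset by construction —
  quartiles must be computed within the group being classified.
- The particle counter has no watershed/declumping; touching nuclei in
  real tissue would be merged, which the renderer's non-overlap
  constraint sidesteps but real fields will not.
- The generator's independence assumptions (above) make recovery rates
  optimistic relative to real postmortem cohorts with RIN and agonal
  confounding.
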