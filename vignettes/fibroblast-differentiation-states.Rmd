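---
title: "Modelling fibroblast differentiation states from single-cell qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fibroblast differentiation states from single-cell qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfib)
```

## The measurement model

Targeted single-cell qPCR reports, for every cell and gene assay, a
quantification cycle Cq or no amplification at all. Two biological signals
are entangled in this readout and the package keeps them separate
throughout:

* the **detection frequency** of a gene in a cell population — the fraction
  of cells with any amplification. At single-cell input amounts a
  transcript present at a few copies regularly fails to amplify, so
  frequency is informative rather than nuisance: genes under switch-like
  regulation (on in some cells, absent in others) change mostly in this
  channel;
* the **expression level** among detected cells — mean log2 relative
  quantity (RQ), where RQ = 2^(cutoff − Cq) references expression to the
  assay's off-scale limit. Genes under transitional regulation change
  mostly here.

No reference-gene normalization is applied; expression is per cell, and
global differences in RNA content are handled explicitly by per-cell
autoscaling where a method requires it (see below). GAPDH serves only as a
sort-efficiency control: cells without GAPDH amplification are removed,
and a plate is flagged when positivity does not clear
`min_gapdh_positivity` (default 0.80).

Key preprocessing parameters (`preprocess_config()`):

| parameter | default | units | meaning |
|---|---|---|---|
| `cq_cutoff` | 28 | cycles | off-scale limit; RQ = 2^(cutoff − Cq). The instrument bound is not universal; 28 cycles is conventional for pre-amplified single-cell panels. |
| `min_gapdh_positivity` | 0.80 | fraction | sort-efficiency bar for the GAPDH gate |
| `imputation_offset` | 1.0 | log2 units | non-detects are imputed this far below the gene's minimum detected value |

Non-detects are exactly 0 on the linear RQ scale and `NA` on the log2
scale. Multivariate methods (correlation, clustering, PCA, SOM) need
complete data, so they operate on the imputed view: each gene's
non-detects are placed one `imputation_offset` below its lowest detected
log2 value (a gene never detected imputes at 0). The detection mask is
never altered by imputation, and all frequency/level statistics are
computed from detected cells only, so imputation influences geometry, not
summaries. Imputed non-detects of a gene are exact ties; Spearman
correlation uses average ranks, which keeps them deterministic.

Three scaling conventions are provided because different analyses need
different invariances: per-gene autoscaling (columns to mean 0, sample SD
1) for PCA across conditions; per-cell autoscaling (rows standardized — a
global normalization) wherever absolute RNA content varies, i.e. for
subpopulation maps and for projecting patient cells; per-gene
mean-centering for clustering heatmaps and for combining datasets measured
on different global scales. Constant rows or columns become zeros with a
warning rather than an error, so degenerate synthetic inputs cannot abort
a run.

## Subpopulation discovery

Cell-to-cell similarity is Spearman's rank correlation over the full
panel, rank-based to be robust to the heavy-tailed log2 values and
invariant to any per-cell affine rescaling. Subgroups come from
agglomerative clustering of the correlation matrix rows (Euclidean
distance, average linkage by default; complete and Ward are available).
`hier_cluster()` is the plain cut-into-k operation. The pipeline instead
uses `curate_subgroups()`, a deterministic version of the manual grouping
an analyst performs on a dendrogram: the tree is cut well below the target
granularity, clusters with at least `min_size` (5) cells count as major
groups, parts are reassembled by centroid proximity until `k` remain, and
stray cells join the nearest centroid. The rationale: average linkage on
183 cells regularly isolates one or two aberrant cells at heights above a
genuine subgroup boundary, so a literal k-cut spends clusters on
outliers; reassembly by centroids is insensitive to that, because split
halves of one subgroup have nearly identical centroids while genuinely
distinct subgroups do not.

A subgroup containing both conditions (minority fraction at least
`split_min_fraction`, default 0.1) is split by cell class — the mixed
cluster observed where normal fibroblasts shade into barely activated
CAFs — and if splitting leaves more than three subgroups per condition,
the smallest surplus group is merged into its nearest same-condition
neighbour (`.consolidate_subgroups`), again mirroring analyst curation.

A 3×2 Kohonen self-organizing map (Gaussian neighbourhood, 1000 online
iterations, prototypes initialized on the first two principal components,
presentation order fixed by the seed) confirms the correlation-derived
subgroups independently. Because neighbouring clusters share units on so
small a grid, the SOM is a qualitative confirmation; its agreement with
the planted partition is typically ARI 0.65–0.87, below the hierarchical
route.

## Bimodal markers

A gene such as ACTA2 can be expressed at two distinct levels within one
condition. `fit_bimodal()` models the detected log2 values (non-detects
excluded — the object modelled is the histogram of expression levels) as
either one Gaussian (closed form) or a sum of two (EM: 10 restarts, the
first initialized by a median split, the rest by random responsibilities;
500 iterations; tolerance 1e-8 on the log-likelihood; component-SD floor
1e-3). The number of components is chosen by BIC, and for two components
the low/high boundary is the point between the means where the posterior
responsibility crosses 0.5, found by root bisection. Cells at or above
the boundary form the high stratum; non-detected cells are low by
definition. Model selection is likelihood-based on raw values, not a fit
to histogram bin counts: with fewer than ~100 values the binning choice
would dominate a count-based fit.

## The differentiation model

For each subgroup k and gene g the pseudo-temporal score is

    score(g, k) = frequency(g, k) × max(level(g, k), 0)

with level the mean log2 RQ over detected cells. Flooring the level at
zero keeps the product's sign interpretable (a gene detected at levels
below the reference limit cannot make a *negative* contribution larger
than an absent gene); zero frequency forces score 0 even where the level
is undefined. Frequencies enter as fractions, not percentages — the
choice affects only the scale of the profile, not any ordering derived
from it. A linear-RQ level variant is available behind a switch.

Marker rules label the subgroups. Among normal-condition subgroups:
stem-like is the one maximizing the mean pluripotency-group score; naive
minimizes a six-gene activation score (ACTA2, COL1A1, TNC, FN1, FAP,
MMP2) among the remainder; the last is primed. Among activated subgroups:
the secretory myofibroblast maximizes the soluble-factor score (CXCL12,
PDGFA, VEGFA, HGF); the ECM-regulating myofibroblast maximizes the
COL1A1/FN1 score among the rest; the remainder is the
proto-myofibroblast. Exact ties break to the lower subgroup id with a
warning. The rule gene lists are an editable argument
(`marker_rules()`), not hard-coded. `order_states()` then arranges the
labelled states into the canonical timeline stem-like → naive → primed →
proto → ECM → secretory.

Gene profiles across the ordered states are themselves clustered
(Euclidean, average linkage) to expose co-regulated archetypes; genes
whose score range exceeds 5× the median range are split out and reported
separately so they cannot dominate the clustering, the analogue of
plotting extreme genes on their own axis.

## Classifying new cells

`fit_reference()` fits a PCA on per-cell autoscaled, imputed reference
cells and places one centroid per state at the mean score of its cells in
the first `n_pcs` components. Test cells are autoscaled per cell with
their own statistics (their global RNA level must not leak into the
projection), centered with the reference means, projected with the
reference loadings — never refitted — and assigned to the nearest
centroid, with ties broken toward the earlier timeline state
(conservative activation calls). `n_pcs` defaults to 3: with six states
the first two components carry the activation and matrix-remodelling
axes while the stem/pluripotency contrast loads on the third, and at two
components nearest-centroid resubstitution cannot reliably separate
stem-like from naive cells. A Mahalanobis rule was rejected because
per-state covariances are poorly estimated at 15–40 cells per state.

## What the synthetic generator emulates

The generator (`reference_config()`, `generate_reference()`,
`patient_config()`, `generate_patient_cohort()`) plants six
differentiation states with per-gene per-state detection probabilities f
and detected-expression means mu (log2 RQ), and draws each cell-gene
reaction as: detected with probability f; if detected, value ~
Normal(mu + cell offset, sqrt(sigma_bio² + sigma_tech²)) with sigma_bio =
1.0 log2 units, sigma_tech = 0.5 cycles, and a per-cell global offset
with SD 0.5 (reference) or 1.0 (patient) log2 units. Values are written
back to Cq via the same RQ convention the pipeline inverts. Detected
draws falling below the detection limit are clamped just above it so the
planted frequencies stay exact; a censoring mode (draws below the limit
become non-detects) exists for robustness tests. The bimodal gene
(ACTA2) draws its component first in activated states — means 5 and 9
log2 RQ, i.e. 4 log2 units of separation, with the low-component weight
falling along the timeline (0.7/0.5/0.4) so the proto-myofibroblast has
the lowest ACTA2 among activated states — and its within-component SD is
0.6 log2 units plus technical noise: the two components *are* the
biological variation of a switch-like regulator, so the generic
biological SD is not stacked on top.

Cohort sizes follow the study design being emulated: 92 control + 91
activated reference cells, 77 normal + 75 CAF patient cells; the
stem-like state holds 10% of the reference cohort and the rest of the
states are near-equal. Patient normal cells are drawn from a
stem/naive/primed mixture (0.15/0.60/0.25) and patient CAFs from a
per-cell interpolation between the primed and proto-myofibroblast
archetypes (weight uniform on 0.25–0.75), emulating early-onset
activation; the recorded true state is the nearer archetype.

The per-gene trajectory table encodes the qualitative biology: activation
markers ramp up along the timeline; COL1A1/FN1/LOX/LOXL2 peak in the ECM
state and the soluble factors in the secretory state; CAV1, CD44 and VIM
ramp down; FSP1 and MMP2 peak in primed cells; pluripotency genes, CCL5
and ALDH1A1 are switch-like and essentially stem-exclusive; HGF switches
on along activation; epithelial genes stay near-silent. Detection
probabilities are deliberately polarized (≥0.9 or ≤0.2 with few
mid-range values) with gradation carried by the means: mid-range
detection probabilities inject Bernoulli noise into every cell's rank
profile and blur subgroup boundaries beyond what clean single-cell qPCR
data shows. Two states are intentionally adjacent — primed and proto —
so that the mixed cluster arises in five-group clustering exactly as a
gradual normal-to-CAF conversion would.

What the generator does **not** emulate: plate spatial effects,
preamplification bias, doublets, cross-hybridization, or condition-level
batch effects; non-detects are true absences by default rather than
censored low expressors. Passing tests on this generator therefore show
that the pipeline recovers structure of the planted kind at realistic
noise, not that real plates are free of those artefacts.

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviations everywhere, so test expectations are
  exact.
* Autoscaling maps constant rows/columns to zeros with a warning.
* PCA loading signs are fixed (largest-magnitude loading positive) to
  make scores reproducible across BLAS implementations.
* Nearest-unit and nearest-centroid ties break to the lowest index /
  earlier timeline state.
* EM that fails to converge in any restart warns and keeps the best
  likelihood; a two-component fit whose means coincide is demoted to one
  component.
* All stochastic steps (generator, SOM order, EM restarts) take explicit
  seeds; reruns of `run_pipeline()` under one configuration are
  bit-identical, which the manifest digests make checkable.

## Problem sizes

The shipped defaults — 183 + 152 cells × 43 genes, five pipeline
replicates in the acceptance script — run the full suite in well under a
minute on one core; they were chosen to match the emulated study design,
which is itself small by sequencing standards but typical for targeted
single-cell qPCR.

## Known limitations

* The six-state labelling assumes three subgroups per condition; runs on
  other designs must supply their own rule set or a reduced state list.
* The significance area of the stratified mean–mean comparison is
  operationalized as the per-gene two-sample t non-rejection region at
  alpha = 0.05 without multiplicity correction (a Benjamini–Hochberg
  option exists but is off by default, matching common practice in
  targeted panels); it is a per-gene statement, not a joint confidence
  region.
* The SOM is confirmatory; on a 3×2 grid neighbouring states can share a
  unit, and its agreement with the planted partition is accordingly lower
  than the hierarchical route's.
* Nearest-centroid classification is hard assignment; cells genuinely
  between states (as interpolated patient CAFs are by construction) are
  forced to the nearer archetype, and no novelty detection flags cells
  unlike any reference state.
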