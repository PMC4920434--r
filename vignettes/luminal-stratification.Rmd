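---
title: "Stratifying luminal breast tumours: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying luminal breast tumours: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumistrat)
```

## The problem

Luminal (ER-positive) breast carcinomas are conventionally split into the
luminal A and luminal B intrinsic subtypes, yet the genes that drive that
split are almost all proliferation-linked and vary continuously across
the cohort, with no bimodality to anchor a boundary. `lumistrat`
implements an alternative stratification: treat all luminal tumours as
one heterogeneous group, first peel off the small subgroup defined by
coordinated over-expression of the 17q12 (*ERBB2*/HER2) gene cluster
("HER2-amplified luminal"), and then order the remaining
"ordinary-luminal" tumours along a survival-linked proliferation
signature, splitting them into four equal quantiles Q1–Q4 for
description and prognosis. Every stage is exercised end-to-end on
synthetic cohorts with planted ground truth, because the cohorts the
approach was developed for are access-controlled.

## Pipeline stages and their models

### Differential filter

Each probe is scored for tumour-versus-control separation under three
alternatives: expression in tumours stochastically (a) lower, (b) higher,
or (c) *bimodally dysregulated* — up in some tumours and down in others.
Cases (a) and (b) are one-sided two-sample rank-sum (Mann–Whitney)
tests. The groups are unpaired and of unequal size, so the signed-rank
variant is not applicable; the rank-sum test is the member of the
Wilcoxon family that fits this design. Case (c) has no canonical
statistic; we operationalise it as a one-sided rank-sum test on absolute
deviations from the control median (tumour deviations larger). This
surrogate is deliberately scale-dependent: a monotone transform of the
data changes which deviations are large, so only cases (a) and (b) are
transform-invariant, and the property tests assert exactly that. The
probe's score is the minimum of the three p-values; under the null this
minimum is stochastically smaller than uniform (the (a) and (b) p-values
are near-complementary), which is why calibration checks are run on the
per-case p-values rather than on the minimum.

No multiple-testing correction is applied inside the filter — the
threshold is geometric (below) — but Benjamini–Hochberg adjusted values
are reported alongside for transparency.

### Knee (maximum-curvature) threshold

Filters are thresholded where the sorted −log10 p profile bends most
sharply. Both axes are rescaled to [0,1]; the profile is smoothed by a
centred moving average and the discrete curvature
κ = |y″| / (1 + y′²)^{3/2} is evaluated by central differences, returning
the curvature argmax (smallest rank on ties). Three numerical choices
matter and are worth recording:

* **Two smoothing passes.** A single moving-average pass of a
  piecewise-linear profile is again piecewise linear: all curvature is
  concentrated in single-point corners, where the steep local slope
  suppresses κ through the (1 + y′²)^{3/2} denominator. A second pass
  rounds the bend into an arc whose moderate-slope flank carries the
  curvature, making the argmax land on the knee rather than on noise.
* **Window = max(5, 2% of the profile length).** Planted-effect profiles
  carry structure on two scales — micro-bends inside the signal plateau
  and the macroscopic elbow where signal meets the noise floor. With a
  narrower window the plateau micro-structure can outweigh the elbow
  (we observed the threshold collapsing from rank ≈ 280 to rank 23 on a
  2,000-probe profile). The window is a function argument, so any other
  bandwidth can be requested.
* **Boundary padding by linear extrapolation.** Shrinking windows at the
  profile ends would bend the smoothed profile and fabricate curvature
  there; linear pads contribute none.

Derivatives are taken at the half-window spacing so that residual
point-to-point wiggles are not differentiated at full resolution. A
strictly linear profile has no knee; the function warns and returns the
boundary-adjacent argmax. Thresholds are always overridable by an
explicit `n_select`, mirroring the fact that a curvature criterion on
real profiles is approximate by nature.

### Sample topology: √JSD distances and MST-kNN

Sample similarity is measured on the selected probes with the square
root of the Jensen–Shannon divergence (base-2 logarithms), a true metric
bounded by 1. Expression vectors are not distributions, so a convention
is required: each sample's vector over the selected probes is shifted to
be non-negative (subtracting the global minimum of the submatrix, if
negative) and normalised to sum 1. This is documented as a choice; any
monotone re-expression of intensities would give a slightly different
geometry.

Clustering prunes the minimum spanning tree of the complete √JSD graph:
an MST edge (u,v) survives iff v is among u's k nearest neighbours *or*
vice versa (the union rule — the more conservative mutual-kNN rule
disconnects far more of the tree, at odds with the observation that
luminal samples remain connected in a single tree). Distance ties are
broken by the lexicographic node-id pair, so the tree is deterministic.
k is the smallest integer for which all control samples land in one
component — the point where within-tumour connections are at least as
tight as those among healthy references. The graph's core is separated
from its periphery by applying the same knee rule to the descending
rescaled betweenness centralities of the largest component (nodes with
zero betweenness — leaves — are never central), and the subtype
composition of the core is tested against the cohort proportion with a
two-sided minimum-likelihood exact binomial test, the convention that
reproduces the worked examples in the acceptance suite (one-sided tails
do not).

t-SNE is used for visualisation only, behind a thin contract over an
established implementation (Rtsne, exact mode, fixed seed, precomputed
distances); 75% confidence ellipses use the normal-theory radius
√(eigenvalue · χ²₀.₇₅(2)) and overlap is decided by boundary-point
membership tests.

### HER2 stratification

The 17q12 cluster is discovered by Spearman correlation of every probe
against the *ERBB2* seed probe across the full training cohort (tumours
and controls; the restriction to tumours is available via an argument,
since the source protocol does not pin this down); membership requires
rho strictly greater than 0.5 — one-sided, so strong anti-correlation
does not qualify. Two centroids over the cluster panel (the mean log2
profile of the luminal group and of the HER2-enriched reference group)
classify every luminal sample by smallest Euclidean distance, ties going
to the first declared group (ordinary-luminal, the conservative call).
Transfer to a second cohort can reuse frozen centroids or recompute them
on the target platform's HER2-enriched group.

### Survival screen and the quantile signature

The survival filter orders samples by each probe's expression and
compares the bottom 30% against the top 30% with a two-group log-rank
test — the quantile size balances Kaplan–Meier reliability (more
samples) against separation capacity (more expression contrast).
Extreme-group sizes use floor, so the groups can never overlap for
q ≤ 0.5. Each surviving probe is tagged by its tumour-vs-control
direction crossed with its prognosis direction (`up_positive`,
`up_negative`, `down_negative`, `down_positive`).

To concentrate on co-expressed biology rather than isolated probes, the
screened panel is clustered: samples are grouped hierarchically on
1 − Spearman profile correlation with average linkage (the linkage is an
argument; "basic hierarchical clustering" does not specify one) and cut
into two clusters, and each probe is scored by a rank-sum contrast
between them. The strict two-way cut errors when a cluster has fewer
than two samples; because average-linkage trees over noisy cohorts
routinely chain off single outlier samples first, the pipeline uses the
`drop_minor` mode, which deepens the cut until two clusters of at least
two samples emerge and contrasts the two *major* clusters, setting
outlier singletons aside. An optional resampling protocol (re-cluster on
80% subsamples) warns when memberships are not reproducible, which is
the signature of a noise panel. The top ten `up_positive` probes by
contrast p (ties to the smaller probe id) form the signature.

Samples are then ordered by their average mid-rank over the panel and
split into four quantiles, Q1 (communally lowest expression) to Q4;
group sizes are ⌈N/4⌉ for the first N mod 4 groups, fixed by the printed
populations that the acceptance suite reproduces (629 → 158/157/157/157).
Per-quantile centroids transfer the stratification to other cohorts by
nearest Euclidean distance. Survival across Q1–Q4 (plus the
HER2-amplified group) is compared with per-group Kaplan–Meier curves,
Greenwood 95% intervals at a ten-year horizon, and a K-group log-rank
test. Ranking on the full screened panel instead of the top ten is the
same code path with a different panel argument.

### Copy-number profiles

Segments are collapsed to gains (gains + amplifications) and losses
(heterozygous + homozygous deletions). A sample counts once per
(cytoband, category) when any of its segments overlaps the band by at
least one base (configurable); denominators are full subgroup sizes.
Per band and category, a K×2 chi-square homogeneity test (no continuity
correction; simulation-based p optional for small counts) asks whether
the subgroup proportions follow the pooled luminal distribution; bands
with zero pooled counts, or with every sample affected, carry no
information and are reported as p = 1 with a degeneracy flag.
Common regions are maximal runs of atomic intervals (the partition
induced by all segment boundaries) where every subgroup's occurrence
rate reaches the threshold (default 50%). The CNA–expression link takes,
per sample and cytoband, the *maximal* segmentation mean over
overlapping segments (a `min` mode exists for loss-oriented analyses,
since taking the maximum for losses is a documented caveat of the
protocol being followed) and emits (band, probe) pairs with Spearman
rho strictly above 0.5 *and* the probe annotated on that same band.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline
assumes, with full ground truth. Defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_tumour`, `n_control` | 680, 144 | training-cohort structure |
| `n_probes` | 2,000 | desk-scale array (the real platform has ~48,800) |
| `frac_diff_up/down/bimodal` | 5% / 5% / 2% | planted tumour–control shifts |
| `effect_size_sd` | 3 | shift in control-SD units (SD = 0.5 log2) |
| `frac_her2_amp`, `her2_block_size` | 8%, 7 | 17q12 amplification block |
| `n_risk_probes` | 50 | probes expressing the latent risk score |
| `hazard_coef` | 0.7 | log-hazard per risk-score SD |
| `censor_rate` | 0.3 | independent exponential censoring |
| `cna_base_rate`, `cna_risk_slope` | 0.15, 0.5 | risk-band event probability |

Controls are Gaussian per probe (means around 7, residual SD 0.5, log2
scale). The HER2 block carries a cohort-wide shared latent factor
(loading 0.4, residual SD 0.35 — the 17q12 genes are tightly
co-regulated in every sample, not only in amplified tumours) plus a
+2 log2 shift in the planted ~8% of tumours; this calibration puts the
block's pairwise Spearman correlations above 0.5 while keeping the
centroid split sharp. Risk probes follow 1 + 0.8·risk in tumours, with
the standardised latent risk score; survival is exponential with
baseline hazard −log(0.75)/3650 per day (75% ten-year survival at
average risk, matching the cohort-wide rates the approach reports) and
log-linear hazard in the risk score, with independent exponential
censoring calibrated to the requested censoring fraction. Risk structure
is planted only when `hazard_coef` is non-zero: the generator defines
"risk probes" by the joint expression–survival link, so a null-hazard
cohort is a clean global null. Copy-number gain/loss segments fall on
designated cytobands of a six-chromosome toy genome with probability
`cna_base_rate + cna_risk_slope · rank01(risk)`; gains feed 1.2× their
segmentation mean back into co-located risk-probe expression, and the
planted HER2 tumours additionally carry a 17q12 amplification segment.

What the generator does *not* emulate: platform-specific probe-level
noise, batch effects, correlated noise between unplanted probes,
non-exponential hazards, subclonal or partial-band copy-number events.
Passing tests therefore demonstrate that the pipeline recovers the
structures it claims to recover under its own modelling assumptions —
not that those assumptions hold on any particular real cohort.

## Problem sizes and determinism

The test suite and the acceptance script run the generator at between
150 and 680 tumours and 400–2,000 probes, sizes at which every planted
structure is comfortably identifiable; the recovery experiments
(differential sensitivity, HER2 recall and fraction, risk-probe recall,
KM monotonicity over 20 seeds) took those sizes from the stated study
conditions. All randomness funnels through explicit integer seeds;
`run_full()` writes a manifest of parameters, seed and MD5 hashes of
every artefact, and two runs with the same seed are byte-identical
(the manifest carries no timestamps).

## Known limitations

* The knee is a geometric criterion; on profiles with no clear elbow it
  degrades to a warned boundary answer, and analyses should prefer an
  explicit `n_select` when the profile is inspected and found flat.
* The bimodal differential case tests dispersion around the control
  median; genuinely shifted-but-tight bimodal mixtures with one mode at
  the control median are invisible to it.
* Expression-to-distribution normalisation for √JSD is a convention;
  geometries under other conventions differ smoothly but not identically.
* The two-cluster contrast assumes the screened panel supports a
  dominant two-group structure; the stability warning, not the p-values,
  is the guard against over-reading a noise panel.
* Cytoband occurrence treats a 1-bp overlap as membership; fractional
  overlap thresholds are available but change rates at band boundaries.
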