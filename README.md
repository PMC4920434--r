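# lumistrat

Stratification of luminal breast tumours from expression, survival and
copy-number profiles.

## The problem

Roughly two thirds of breast cancers are luminal (ER-positive), and the
standard molecular split into luminal A and luminal B rests almost
entirely on proliferation-linked genes whose expression varies
*continuously* across the cohort — there is no bimodality to anchor a
boundary, and samples near the A/B interface are classified essentially
arbitrarily. `lumistrat` implements an alternative stratification for
analysts working with bulk expression cohorts (log2 microarray-style
intensities with healthy-tissue controls, survival follow-up and
per-sample copy-number segments):

1. **Differential filter.** Every probe is scored for tumour-vs-control
   separation by the minimum p over three one-sided rank-sum
   alternatives — tumours lower, higher, or bimodally dysregulated
   (tested on absolute deviations from the control median) — and the
   probe ranking is cut where the sorted −log10 p curve has maximal
   curvature κ = |y″|/(1 + y′²)^{3/2} (the "knee").
2. **Sample topology.** Samples become discrete distributions over the
   selected probes; pairwise distances are √JSD (square root of the
   Jensen–Shannon divergence, base-2 logs — a true metric bounded
   by 1). The minimum spanning tree is pruned to edges present in the
   k-nearest-neighbour graph, with k the smallest integer that joins
   all controls into one component. Betweenness centrality splits the
   graph into core and periphery (knee rule again), and core
   composition is tested with a two-sided minimum-likelihood exact
   binomial test against the cohort proportion. t-SNE with 75%
   confidence ellipses provides the companion visualisation.
3. **HER2-amplified luminal.** The 17q12 co-expression cluster is
   discovered by Spearman correlation against the *ERBB2* probe
   (members: rho > 0.5); luminal and HER2-enriched mean-expression
   centroids over that panel classify every luminal tumour by nearest
   Euclidean distance into *HER2-amplified luminal* (~8% of luminal
   cases, poor prognosis) vs *ordinary luminal*.
4. **Risk signature.** For ordinary-luminal tumours, a survival filter
   compares the bottom-30% vs top-30% expression groups per probe with
   a log-rank test (knee threshold); the screened panel is reduced to
   its top ten co-expressed, proliferation-linked (`up_positive`)
   probes via a two-cluster hierarchical contrast; samples are ordered
   by average rank over the panel and split into equal quantiles
   **Q1–Q4**, whose Kaplan–Meier curves separate monotonically.
   Centroids transfer the quantiles to other cohorts.
5. **Copy-number profiles.** Per-cytoband gain/loss occurrence rates
   per subgroup, K×2 chi-square homogeneity tests, common regions
   altered in ≥50% of every subgroup, and Spearman links between
   per-band maximal segmentation means and co-located probe expression.

The cohorts this methodology targets are access-controlled, so the
package ships a seeded synthetic-cohort generator
(`generate_cohort()`) that emulates their structure — planted
differential probes, a co-amplified HER2 block in 8% of tumours, a
continuous risk gradient with exponential survival, risk-linked CNA
segments — with full ground truth, making every stage testable.

## Worked example

```r
library(lumistrat)

g <- generate_cohort(cohort_config(n_tumour = 200, n_control = 60,
                                   n_probes = 800, n_risk_probes = 30,
                                   seed = 42))
co <- g$cohort
co
#> expression_cohort: 800 probes x 260 samples (60 controls, 200 tumours)

fr <- differential_filter(co)
fr
#> filter_result: 800 probes, 148 selected (threshold p = 0.00796)

seed_probe <- co$probe_meta$probe_id[co$probe_meta$gene_symbol == "ERBB2"]
st <- stratify_luminal(co, tumour_ids(co),
                       her2_enriched_ids = g$truth$planted_her2_samples,
                       seed_probe = seed_probe)
st
#> her2_stratification: 200 luminal samples, 8.5% HER2-amplified

ordinary <- st$assignment$sample_id[st$assignment$group == "ordinary_luminal"]
sub <- subset_cohort(co, samples = c(ordinary, control_ids(co)))
sf <- survival_filter(sub, candidate_probes = fr$probe_id[fr$selected])
cc <- two_cluster_contrast(co, ordinary, sf$probe_id[sf$selected],
                           drop_minor = TRUE)
panel <- select_top_panel(cc$contrast,
                          group_tags = setNames(sf$group_tag, sf$probe_id))
qa <- quantile_split(average_rank_order(co, ordinary, panel))
grp <- setNames(as.character(qa$quantile), qa$sample_id)
sm <- co$sample_meta
compare_survival(grp, setNames(sm$survival_time, sm$sample_id),
                 setNames(sm$event, sm$sample_id))
#> survival_comparison at 3650 days (log-rank p = 3.6e-10):
#>  group  n  survival     lower     upper
#>     Q1 46 0.8769841 0.7814170 0.9842391
#>     Q2 46 0.7960976 0.6855766 0.9244355
#>     Q3 46 0.6994115 0.5744255 0.8515925
#>     Q4 45 0.5476190 0.4183452 0.7168400
```

Reading the output: the differential filter's knee keeps 148 of 800
probes (the cohort has 96 planted differential probes plus the HER2
block and 30 risk probes); the centroid split calls 8.5% of luminal
tumours HER2-amplified against a planted rate of 8%; and the
quantiles' ten-year Kaplan–Meier survival decreases monotonically from
88% (Q1) to 55% (Q4) with an overall log-rank p of 3.6 × 10⁻¹⁰ —
the continuous risk gradient the signature is built to expose.

## The analysis workflow

The `analysis/` directory holds the numbered drivers that run the full
study on simulated training and validation cohorts, writing tables and
figures under `results/`:

```sh
Rscript analysis/01_simulate.R             # cohorts + ground truth, all file formats
Rscript analysis/02_differential_filter.R  # three-case filter + knee threshold
Rscript analysis/03_manifold.R             # sqrt-JSD, MST-kNN, core/periphery, t-SNE
Rscript analysis/04_her2.R                 # 17q12 cluster, centroids, stratification
Rscript analysis/05_signature.R            # survival screen, top-ten panel, Q1-Q4 KM
Rscript analysis/06_cna.R                  # cytoband profiles, common regions, links
```

Each script states what it found (recovery of planted structure,
selected thresholds, ellipse overlaps, KM separation, flagged
cytobands) on standard output. `run_full()` chains the same stages in
one call and writes a seeded manifest with MD5 hashes of every
artefact, so identical seeds give byte-identical runs.

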