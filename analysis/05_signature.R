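#!/usr/bin/env Rscript
# Risk signature for the ordinary-luminal tumours: survival filter on
# the differential probes, two-cluster hierarchical contrast, top-ten
# panel, average-rank ordering into quantiles Q1..Q4, per-quantile
# centroids, Kaplan-Meier comparison, and the centroid transfer to the
# validation cohort.

library(lumistrat)

dat <- "results/data"
out <- "results/05_signature"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

read_set <- function(tag) read_expression(
  file.path(dat, paste0(tag, "_expression.tsv")),
  file.path(dat, paste0(tag, "_probes.tsv")),
  file.path(dat, paste0(tag, "_samples.tsv")))
tr <- read_set("training")
va <- read_set("validation")
fr <- read.delim("results/02_differential/differential_filter.tsv")
assign_tr <- read.delim("results/04_her2/training_assignment.tsv")
ordinary <- assign_tr$sample_id[assign_tr$group == "ordinary_luminal"]
her2_amp <- setdiff(assign_tr$sample_id, ordinary)

sub <- subset_cohort(tr, samples = c(ordinary, control_ids(tr)))
sf <- survival_filter(sub, candidate_probes = fr$probe_id[fr$selected])
write_filter_result(sf, file.path(out, "survival_filter.tsv"))
message(sprintf("survival filter: %d of %d probes pass the knee; tags: %s",
                sum(sf$selected), nrow(sf),
                paste(names(table(sf$group_tag[sf$selected])),
                      table(sf$group_tag[sf$selected]), collapse = " ")))

cc <- two_cluster_contrast(tr, ordinary, sf$probe_id[sf$selected],
                           drop_minor = TRUE)
panel <- select_top_panel(cc$contrast,
                          group_tags = setNames(sf$group_tag, sf$probe_id),
                          n_top = 10)
message("top-ten signature panel: ", paste(panel, collapse = ", "))
write.table(data.frame(probe_id = panel), file.path(out, "top_panel.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

qa <- quantile_split(average_rank_order(tr, ordinary, panel))
cen <- quantile_centroids(tr, qa, panel)
write_centroid_model(cen, file.path(out, "quantile_centroids.tsv"))
write.table(qa, file.path(out, "training_quantiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

km_report <- function(cohort, grp, tag) {
  sm <- cohort$sample_meta
  cs <- compare_survival(grp, setNames(sm$survival_time, sm$sample_id),
                         setNames(sm$event, sm$sample_id))
  message(sprintf("%s 10-year survival: %s; log-rank p = %.3g", tag,
                  paste(sprintf("%s %.0f%%", cs$at_horizon$group,
                                100 * cs$at_horizon$survival), collapse = ", "),
                  cs$logrank_p))
  write.table(cs$at_horizon, file.path(out, paste0(tag, "_km10.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  plot_km_svg(cs, file.path(out, paste0(tag, "_km.svg")))
  cs
}
grp_tr <- c(setNames(as.character(qa$quantile), qa$sample_id),
            setNames(rep("HER2_amp", length(her2_amp)), her2_amp))
km_report(tr, grp_tr, "training")

# transfer: validation samples assigned by shortest Euclidean distance
assign_va <- read.delim("results/04_her2/validation_assignment.tsv")
ord_va <- assign_va$sample_id[assign_va$group == "ordinary_luminal"]
qv <- quantile_assign_by_centroid(va, ord_va, cen)
write.table(qv, file.path(out, "validation_quantiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
grp_va <- setNames(as.character(qv$quantile), qv$sample_id)
km_report(va, grp_va, "validation")

# the 600-probe-style variant: rank on the full survival-filter panel
qa_all <- quantile_split(average_rank_order(tr, ordinary,
                                            sf$probe_id[sf$selected]))
grp_all <- setNames(as.character(qa_all$quantile), qa_all$sample_id)
km_report(tr, grp_all, "training_full_panel")
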