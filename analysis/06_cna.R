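#!/usr/bin/env Rscript
# Copy-number profiles of the luminal subgroups: per-cytoband gain/loss
# occurrence rates, K-sample proportion tests, regions altered in >= 50%
# of every subgroup, and the correlation of per-band maximal segmentation
# means with co-located survival-probe expression.

library(lumistrat)

dat <- "results/data"
out <- "results/06_cna"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tr <- read_expression(file.path(dat, "training_expression.tsv"),
                      file.path(dat, "training_probes.tsv"),
                      file.path(dat, "training_samples.tsv"))
seg <- read_cna_segments(file.path(dat, "training_segments.tsv"))
cb <- read_cytobands(file.path(dat, "cytobands.txt"))
qa <- read.delim("results/05_signature/training_quantiles.tsv")
her2 <- read.delim("results/04_her2/training_assignment.tsv")
amp <- her2$sample_id[her2$group == "her2_amplified_luminal"]
sf <- read.delim("results/05_signature/survival_filter.tsv")

grp <- c(setNames(as.character(qa$quantile), qa$sample_id),
         setNames(rep("HER2_amp", length(amp)), amp))

prof <- cytoband_occurrence(seg, cb, grp)
tests <- proportion_test_per_band(prof)
write.table(prof, file.path(out, "occurrence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tests, file.path(out, "proportion_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- tests[!tests$degenerate & tests$p_adj_bh < 0.05, ]
message(sprintf("%d band/category combinations differ across subgroups (BH < 0.05):",
                nrow(sig)))
print(sig[order(sig$p_value), c("chromosome", "band_name", "category",
                                "neglog10_p")][1:min(8, nrow(sig)), ])
plot_cna_profile_svg(prof, tests, file.path(out, "cna_profile.svg"))

for (cat in c("gain", "loss")) {
  cr <- common_regions(seg, grp, cat, min_rate = 0.5)
  write.table(cr, file.path(out, paste0("common_", cat, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("%s regions at >= 50%% occurrence in every subgroup: %d",
                  cat, nrow(cr)))
}

link <- cna_expression_link(seg, tr, sf$probe_id[sf$selected], cb,
                            rho_min = 0.5)
write.table(link, file.path(out, "expression_link.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("probes with rho > 0.5 to their own band's maximal seg-mean: %d",
                nrow(link)))
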