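#!/usr/bin/env Rscript
# Differential filter: score every probe's tumour/control separation
# under the three alternatives (lower / higher / bimodally dysregulated),
# rank by minimal p and place the threshold at the maximum-curvature knee
# of the -log10 p profile.

library(lumistrat)

dat <- "results/data"
out <- "results/02_differential"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

co <- read_expression(file.path(dat, "training_expression.tsv"),
                      file.path(dat, "training_probes.tsv"),
                      file.path(dat, "training_samples.tsv"))
truth <- read.delim(file.path(dat, "training_truth_diff.tsv"))

fr <- differential_filter(co)
write_filter_result(fr, file.path(out, "differential_filter.tsv"))
message(sprintf("knee threshold at rank %d of %d (p = %.3g)",
                attr(fr, "threshold_rank"), nrow(fr), attr(fr, "threshold_p")))
sel <- fr$probe_id[fr$selected]
message(sprintf("planted differential probes recovered: %.1f%% (%d planted)",
                100 * mean(truth$probe_id %in% sel), nrow(truth)))

svg(file.path(out, "knee_profile.svg"), width = 6, height = 4)
plot(fr$rank, fr$neglog10_p, type = "l", xlab = "probe rank",
     ylab = "-log10 p", main = "Differential filter profile")
abline(v = attr(fr, "threshold_rank"), col = "firebrick", lty = 2)
dev.off()

# probes diverging in different directions from controls, contrasting the
# two tumour subtype labels over the selected probes
labels <- setNames(co$sample_meta$subtype_label, co$sample_meta$sample_id)
lumA <- names(labels)[labels == "lumA"]
lumB <- names(labels)[labels == "lumB"]
div <- divergent_direction_probes(co, lumA, lumB, sel)
message(sprintf("divergent-direction probes among selected: %d of %d (%.1f%%)",
                length(div), length(sel), 100 * length(div) / length(sel)))
write.table(data.frame(probe_id = div), file.path(out, "divergent_probes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
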