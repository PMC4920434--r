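#!/usr/bin/env Rscript
# Simulate a training and a validation cohort with the structure the
# downstream analyses assume (tumour/control shifts, a co-amplified
# HER2-locus block in ~8% of tumours, a proliferation-like risk gradient
# tied to survival, risk-linked copy-number events), and write every
# artefact format so the later stages run off disk exactly as they would
# on real exports.

library(lumistrat)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

write_set <- function(tag, seed) {
  g <- generate_cohort(cohort_config(seed = seed))
  write_expression(g$cohort,
                   file.path(out, paste0(tag, "_expression.tsv")),
                   file.path(out, paste0(tag, "_probes.tsv")),
                   file.path(out, paste0(tag, "_samples.tsv")))
  write_cna_segments(g$segments, file.path(out, paste0(tag, "_segments.tsv")))
  write_cytobands(g$cytobands, file.path(out, "cytobands.txt"))
  # ground truth goes to TSV (no binary artefacts)
  write.table(g$truth$planted_diff_probes,
              file.path(out, paste0(tag, "_truth_diff.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = g$truth$planted_her2_samples),
              file.path(out, paste0(tag, "_truth_her2.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(probe_id = g$truth$planted_risk_probes),
              file.path(out, paste0(tag, "_truth_risk.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s cohort: %d probes x %d samples, %d CNA segments, seed %d",
                  tag, nrow(g$cohort$values), ncol(g$cohort$values),
                  nrow(g$segments), seed))
  g
}

tr <- write_set("training", seed = 101)
va <- write_set("validation", seed = 102)

message("planted HER2 fraction (training): ",
        round(length(tr$truth$planted_her2_samples) /
                length(tumour_ids(tr$cohort)), 4))
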