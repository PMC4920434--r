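#!/usr/bin/env Rscript
# HER2 stratification: discover the 17q12 co-expression cluster around
# the ERBB2 probe, build luminal and HER2-amplified centroids over the
# cluster panel, split the luminal tumours by nearest centroid, and
# transfer the frozen centroids to the validation cohort.

library(lumistrat)

dat <- "results/data"
out <- "results/04_her2"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

read_set <- function(tag) read_expression(
  file.path(dat, paste0(tag, "_expression.tsv")),
  file.path(dat, paste0(tag, "_probes.tsv")),
  file.path(dat, paste0(tag, "_samples.tsv")))
tr <- read_set("training")
va <- read_set("validation")
truth_tr <- read.delim(file.path(dat, "training_truth_her2.tsv"))$sample_id
truth_va <- read.delim(file.path(dat, "validation_truth_her2.tsv"))$sample_id

seed_probe <- tr$probe_meta$probe_id[tr$probe_meta$gene_symbol == "ERBB2"][1]
cl <- discover_cluster(tr, seed_probe, rho_min = 0.5)
message("HER2 co-expression cluster (rho > 0.5):")
print(cl)
write.table(cl, file.path(out, "her2_cluster.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# the planted amplified samples play the HER2-enriched reference role
st <- stratify_luminal(tr, tumour_ids(tr), her2_enriched_ids = truth_tr,
                       seed_probe = seed_probe)
write_centroid_model(st$model, file.path(out, "her2_centroids.tsv"))
write.table(st$assignment, file.path(out, "training_assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
amp <- st$assignment$sample_id[st$assignment$group == "her2_amplified_luminal"]
message(sprintf("training: %.2f%% HER2-amplified luminal (planted 8%%), recall %.1f%%",
                100 * st$fraction_amplified,
                100 * mean(truth_tr %in% amp)))

# validation transfer with the *same* centroids
sv <- stratify_luminal(va, tumour_ids(va), model = st$model)
write.table(sv$assignment, file.path(out, "validation_assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
amp_v <- sv$assignment$sample_id[sv$assignment$group == "her2_amplified_luminal"]
message(sprintf("validation (frozen centroids): %.2f%% amplified, recall %.1f%%",
                100 * sv$fraction_amplified,
                100 * mean(truth_va %in% amp_v)))
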