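#!/usr/bin/env Rscript
# Sample topology on the differential-filter probes: sqrt Jensen-Shannon
# distances, MST-kNN clustering with the smallest k that joins the
# controls, betweenness core/periphery analysis with a binomial
# enrichment test, and a t-SNE embedding with 75% confidence ellipses.

library(lumistrat)

dat <- "results/data"
out <- "results/03_manifold"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

co <- read_expression(file.path(dat, "training_expression.tsv"),
                      file.path(dat, "training_probes.tsv"),
                      file.path(dat, "training_samples.tsv"))
fr <- read.delim("results/02_differential/differential_filter.tsv")
sel <- fr$probe_id[fr$selected]

D <- js_distance_matrix(co, sel)
write.table(data.frame(sample_id = rownames(D), round(D, 10)),
            file.path(out, "js_distance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

k <- select_k(D, control_ids(co))
g <- build_mst_knn(D, k)
message(sprintf("selected k = %d; %d components (largest: %d nodes)",
                k, max(g$membership), max(table(g$membership))))

split <- centrality_split(g)
labels <- setNames(co$sample_meta$subtype_label, co$sample_meta$sample_id)
labels[labels == "control"] <- NA
enr <- central_enrichment(g, labels, "lumB")
message(sprintf("central region: %d of %d labelled lumB (cohort %.1f%%), p = %.3g",
                enr$count_in_central, enr$n_central,
                100 * enr$cohort_proportion, enr$p_value))
write_mst_knn_graphml(g, file.path(out, "mst_knn.graphml"),
                      central_ids = split$central_ids)

# robustness of the arrangement to halving/doubling the probe count
fr_obj <- fr; class(fr_obj) <- c("filter_result", "data.frame")
tab <- knn_robustness(co, fr_obj, base_n = length(sel),
                      control_ids = control_ids(co),
                      labels = labels, target_label = "lumB")
write.table(tab, file.path(out, "knn_robustness.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("probe-count robustness:")
print(tab)

# t-SNE embedding with confidence ellipses per class
emb <- embed_tsne(D, seed = 101, perplexity = 30, max_iter = 500)
write.table(data.frame(sample_id = rownames(emb), emb),
            file.path(out, "tsne_embedding.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cls <- ifelse(co$sample_meta$is_control, "control",
              co$sample_meta$subtype_label)
ell <- lapply(split(rownames(emb), cls), function(ids)
  confidence_ellipse(emb[ids, , drop = FALSE], level = 0.75))
ov <- ellipses_overlap(ell$lumA, ell$lumB)
ov_ctrl <- ellipses_overlap(ell$lumA, ell$control)
message(sprintf("75%% ellipses: lumA/lumB overlap = %s, lumA/control overlap = %s",
                ov, ov_ctrl))

svg(file.path(out, "tsne.svg"), width = 6, height = 6)
cols <- c(control = "black", lumA = "yellowgreen", lumB = "coral")
plot(emb, col = cols[cls], pch = 19, cex = 0.6, main = "t-SNE (sqrt JSD)")
for (nm in names(ell)) {
  b <- lumistrat:::.ellipse_boundary(ell[[nm]])
  lines(b, col = cols[nm], lwd = 2)
}
dev.off()
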