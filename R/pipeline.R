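#' Pipeline configuration
#'
#' Collects every stage parameter of [run_full()] in one validated list.
#' Either a synthetic-cohort configuration ([cohort_config()]) or paths
#' to on-disk inputs (expression TSVs, SEG-like CNA TSV, cytoband file)
#' must be supplied.
#'
#' @param cohort_cfg a [cohort_config()] for a synthetic run (NULL when
#'   reading from files).
#' @param paths named list with `matrix`, `probe_meta`, `sample_meta`,
#'   `segments`, `cytobands` (ignored when `cohort_cfg` is given).
#' @param q_surv extreme-quantile size of the survival filter.
#' @param rho_min correlation threshold for the HER2 cluster and the
#'   CNA-expression link.
#' @param n_groups number of risk quantiles.
#' @param n_top signature panel size.
#' @param k_max largest k tried by [select_k()].
#' @param n_diff,n_surv optional explicit filter thresholds
#'   (NULL = knee).
#' @param knee_window smoothing window for [knee_threshold()].
#' @param run_tsne compute the t-SNE embedding stage.
#' @param tsne_perplexity,horizon_days further stage parameters.
#' @param seed pipeline seed (funnels every stochastic step).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_cfg = NULL, paths = NULL, q_surv = 0.30,
                            rho_min = 0.5, n_groups = 4L, n_top = 10L,
                            k_max = 30L, n_diff = NULL, n_surv = NULL,
                            knee_window = NULL, run_tsne = TRUE,
                            tsne_perplexity = 30, horizon_days = 3650,
                            seed = 1L) {
  if (is.null(cohort_cfg) && is.null(paths))
    stop("supply either cohort_cfg or paths")
  if (!is.null(paths)) {
    need <- c("matrix", "probe_meta", "sample_meta", "segments", "cytobands")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("paths missing: ", paste(miss, collapse = ", "))
  }
  stopifnot(q_surv > 0, q_surv <= 0.5, n_groups >= 2L, n_top >= 1L, k_max >= 1L)
  structure(list(cohort_cfg = cohort_cfg, paths = paths, q_surv = q_surv,
                 rho_min = rho_min, n_groups = as.integer(n_groups),
                 n_top = as.integer(n_top), k_max = as.integer(k_max),
                 n_diff = n_diff, n_surv = n_surv, knee_window = knee_window,
                 run_tsne = run_tsne, tsne_perplexity = tsne_perplexity,
                 horizon_days = horizon_days, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (`cohort_cfg` as a nested map of [cohort_config()]
#'   arguments).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort_cfg)) y$cohort_cfg <- do.call(cohort_config, y$cohort_cfg)
  do.call(pipeline_config, y)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full stratification pipeline
#'
#' Stage order: (1) load or simulate the cohort; (2) differential
#' filter; (3) manifold diagnostics (sqrt-JSD distances, k selection,
#' MST-kNN, core/periphery enrichment, optional t-SNE); (4) HER2
#' stratification of the luminal tumours; (5) survival filter on the
#' ordinary-luminal group; (6) two-cluster contrast and top-panel
#' selection; (7) average-rank quantiles, centroids and Kaplan-Meier
#' comparison; (8) cytoband CNA profiles. Every stage writes its TSV
#' outputs into `out_dir` and a manifest (parameters, seed, stage list,
#' file MD5 hashes — no timestamps, so equal seeds give equal
#' manifests) is written last.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  res <- list()
  stage <- function(name, expr) {
    r <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    message(sprintf("[%s] done", name))
    r
  }

  res$inputs <- stage("load_inputs", {
    if (!is.null(config$cohort_cfg)) {
      generate_cohort(config$cohort_cfg)
    } else {
      list(cohort = read_expression(config$paths$matrix, config$paths$probe_meta,
                                    config$paths$sample_meta),
           segments = read_cna_segments(config$paths$segments),
           cytobands = read_cytobands(config$paths$cytobands),
           truth = NULL, config = NULL)
    }
  })
  cohort <- res$inputs$cohort
  set.seed(config$seed)

  res$diff <- stage("differential_filter", {
    r <- differential_filter(cohort, n_select = config$n_diff,
                             window = config$knee_window)
    write_filter_result(r, file.path(out_dir, "differential_filter.tsv"))
    r
  })
  diff_probes <- res$diff$probe_id[res$diff$selected]

  res$manifold <- stage("manifold_graph", {
    D <- js_distance_matrix(cohort, diff_probes)
    ctl <- control_ids(cohort)
    k <- select_k(D, ctl, k_max = config$k_max)
    g <- build_mst_knn(D, k)
    labels <- stats::setNames(cohort$sample_meta$subtype_label,
                              cohort$sample_meta$sample_id)
    labels[labels %in% c("control", "unknown")] <- NA
    split <- centrality_split(g)
    enr <- central_enrichment(g, labels, "lumB")
    emb <- NULL
    if (isTRUE(config$run_tsne)) {
      perp <- min(config$tsne_perplexity, floor((nrow(D) - 1) / 3))
      emb <- embed_tsne(D, seed = config$seed, perplexity = perp)
      .write_tsv(data.frame(sample_id = rownames(emb), emb),
                 file.path(out_dir, "tsne_embedding.tsv"))
    }
    .write_tsv(data.frame(sample_id = rownames(D), round(D, 10)),
               file.path(out_dir, "js_distance.tsv"))
    write_mst_knn_graphml(g, file.path(out_dir, "mst_knn.graphml"),
                          central_ids = split$central_ids)
    list(D = D, k = k, graph = g, split = split, enrichment = enr,
         embedding = emb)
  })

  res$her2 <- stage("stratify_luminal", {
    lum <- cohort$sample_meta$sample_id[
      cohort$sample_meta$subtype_label %in% c("lumA", "lumB")]
    her2e <- cohort$sample_meta$sample_id[
      cohort$sample_meta$subtype_label == "her2e"]
    seed_probe <- .default_seed_probe(cohort)
    # without a labelled HER2-enriched reference group, the planted-block
    # reference is the discovered cluster's top tumours; with labels, use them
    if (!length(her2e)) {
      cl <- discover_cluster(cohort, seed_probe, rho_min = config$rho_min)
      ord <- average_rank_order(cohort, lum, cl$probe_id)
      n_ref <- max(5L, round(0.05 * length(lum)))
      her2e <- utils::tail(ord$sample_id, n_ref)
    }
    s <- stratify_luminal(cohort, luminal_ids = lum,
                          her2_enriched_ids = her2e,
                          seed_probe = seed_probe, rho_min = config$rho_min)
    .write_tsv(s$assignment, file.path(out_dir, "her2_stratification.tsv"))
    write_centroid_model(s$model, file.path(out_dir, "her2_centroids.tsv"))
    s
  })
  ordinary <- res$her2$assignment$sample_id[
    res$her2$assignment$group == "ordinary_luminal"]

  res$surv <- stage("survival_filter", {
    sub <- subset_cohort(cohort, samples = c(ordinary, control_ids(cohort)))
    r <- survival_filter(sub, candidate_probes = diff_probes,
                         n_select = config$n_surv, q = config$q_surv,
                         window = config$knee_window)
    write_filter_result(r, file.path(out_dir, "survival_filter.tsv"))
    r
  })
  surv_probes <- res$surv$probe_id[res$surv$selected]

  res$signature <- stage("signature_panel", {
    cc <- two_cluster_contrast(cohort, ordinary, surv_probes,
                               drop_minor = TRUE)
    tags <- stats::setNames(res$surv$group_tag, res$surv$probe_id)
    panel <- select_top_panel(cc$contrast, group_tags = tags,
                              n_top = config$n_top)
    .write_tsv(data.frame(probe_id = panel), file.path(out_dir, "top_panel.tsv"))
    list(contrast = cc, panel = panel)
  })

  res$quantiles <- stage("quantile_split", {
    ord <- average_rank_order(cohort, ordinary, res$signature$panel)
    qa <- quantile_split(ord, n_groups = config$n_groups)
    cen <- quantile_centroids(cohort, qa, res$signature$panel)
    .write_tsv(qa, file.path(out_dir, "quantile_assignment.tsv"))
    write_centroid_model(cen, file.path(out_dir, "quantile_centroids.tsv"))
    list(assignment = qa, centroids = cen)
  })

  res$survival_comparison <- stage("compare_survival", {
    qa <- res$quantiles$assignment
    grp <- stats::setNames(as.character(qa$quantile), qa$sample_id)
    amp <- res$her2$assignment$sample_id[
      res$her2$assignment$group == "her2_amplified_luminal"]
    if (length(amp))
      grp <- c(grp, stats::setNames(rep("HER2_amp", length(amp)), amp))
    sm <- cohort$sample_meta
    st <- stats::setNames(sm$survival_time, sm$sample_id)
    ev <- stats::setNames(sm$event, sm$sample_id)
    cs <- compare_survival(grp, st, ev, horizon_days = config$horizon_days)
    .write_tsv(cs$at_horizon, file.path(out_dir, "km_at_horizon.tsv"))
    plot_km_svg(cs, file.path(out_dir, "km_curves.svg"))
    cs
  })

  res$cna <- stage("cna_profiles", {
    qa <- res$quantiles$assignment
    grp <- stats::setNames(as.character(qa$quantile), qa$sample_id)
    amp <- res$her2$assignment$sample_id[
      res$her2$assignment$group == "her2_amplified_luminal"]
    if (length(amp))
      grp <- c(grp, stats::setNames(rep("HER2_amp", length(amp)), amp))
    prof <- cytoband_occurrence(res$inputs$segments, res$inputs$cytobands,
                                grp)
    tests <- proportion_test_per_band(prof)
    link <- cna_expression_link(res$inputs$segments, cohort, surv_probes,
                                res$inputs$cytobands, rho_min = config$rho_min)
    .write_tsv(prof, file.path(out_dir, "cna_occurrence.tsv"))
    .write_tsv(tests, file.path(out_dir, "cna_proportion_tests.tsv"))
    .write_tsv(link, file.path(out_dir, "cna_expression_link.tsv"))
    plot_cna_profile_svg(prof, tests, file.path(out_dir, "cna_profile.svg"))
    list(profile = prof, tests = tests, link = link)
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(out_dir), "manifest.json"))
    hashes <- tools::md5sum(file.path(out_dir, files))
    m <- list(package_version = as.character(utils::packageVersion("lumistrat")),
              seed = config$seed,
              parameters = config[setdiff(names(config), c("cohort_cfg", "paths"))],
              cohort_cfg = if (!is.null(config$cohort_cfg))
                unclass(config$cohort_cfg) else NULL,
              stages = stages,
              files = as.list(stats::setNames(unname(hashes), files)))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })
  res$manifest <- manifest
  invisible(res)
}

# the HER2/ERBB2 probe when annotated, otherwise the first probe on the
# 17q12-like band
.default_seed_probe <- function(cohort) {
  hit <- which(cohort$probe_meta$gene_symbol %in% c("ERBB2", "HER2"))
  if (length(hit)) return(cohort$probe_meta$probe_id[hit[1L]])
  hit <- which(cohort$probe_meta$chromosome == "chr17" &
                 cohort$probe_meta$cytoband == "q12")
  if (length(hit)) return(cohort$probe_meta$probe_id[hit[1L]])
  stop("no HER2 seed probe annotated in the cohort")
}
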