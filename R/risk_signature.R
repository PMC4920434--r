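#' Two-cluster hierarchical contrast over a probe panel
#'
#' Samples are clustered hierarchically on the distance
#' `1 - Spearman(sample profiles over the panel)` (average linkage by
#' default), the tree is cut into exactly two clusters, and every probe
#' of the panel is scored by a two-sided two-sample rank-sum test
#' between the clusters.
#'
#' An optional stability check re-clusters on random 80% subsamples and
#' warns when, on average, more than 25% of the retained samples change
#' cluster: with a pure-noise panel, two-cluster memberships are not
#' reproducible and the contrast should not be trusted.
#'
#' @param cohort an [expression_cohort()].
#' @param sample_ids >= 4 sample ids to cluster.
#' @param probe_panel >= 2 probe ids.
#' @param linkage hclust linkage (default "average").
#' @param drop_minor with the strict default (FALSE) the tree is cut into
#'   exactly two clusters and a singleton cluster is an error. With TRUE
#'   the cut is deepened (k = 2, 3, ...) until the two largest clusters
#'   both have at least 2 samples, and the contrast uses those two
#'   *major* clusters, leaving outlier singletons aside — average-linkage
#'   trees over noisy samples routinely chain off single outliers first.
#' @param stability_check run the resampling stability protocol.
#' @param n_resample resamples for the stability check (default 20).
#' @return list with `clusterA_ids`, `clusterB_ids` (A is the larger
#'   cluster), `contrast` (data.frame probe_id, p_contrast) and
#'   `stability` (mean membership-change fraction, or NA).
#' @export
two_cluster_contrast <- function(cohort, sample_ids, probe_panel,
                                 linkage = "average", drop_minor = FALSE,
                                 stability_check = FALSE, n_resample = 20L) {
  stopifnot(length(probe_panel) >= 2L, length(sample_ids) >= 4L)
  X <- cohort$values[probe_panel, sample_ids, drop = FALSE]
  cut_k <- function(cols, k) {
    R <- suppressWarnings(stats::cor(X[, cols, drop = FALSE], method = "spearman"))
    hc <- stats::hclust(stats::as.dist(1 - R), method = linkage)
    stats::cutree(hc, k = k)
  }
  cut2 <- function(cols) {
    memb <- cut_k(cols, 2L)
    if (!drop_minor) return(memb)
    for (k in 2L:min(10L, length(cols) - 1L)) {
      if (k > 2L) memb <- cut_k(cols, k)
      sizes <- sort(table(memb), decreasing = TRUE)
      if (length(sizes) >= 2L && sizes[2L] >= 2L) {
        out <- rep(NA_integer_, length(memb))
        out[memb == as.integer(names(sizes)[1L])] <- 1L
        out[memb == as.integer(names(sizes)[2L])] <- 2L
        return(out)
      }
    }
    memb
  }
  memb <- cut2(seq_along(sample_ids))
  a <- sample_ids[!is.na(memb) & memb == 1L]
  b <- sample_ids[!is.na(memb) & memb == 2L]
  if (min(length(a), length(b)) < 2L)
    stop("a cluster of size < 2 emerged; the panel does not support a ",
         "two-cluster contrast")
  if (length(b) > length(a)) { tmp <- a; a <- b; b <- tmp }
  p <- vapply(probe_panel, function(pid) {
    suppressWarnings(stats::wilcox.test(cohort$values[pid, a],
                                        cohort$values[pid, b])$p.value)
  }, numeric(1L))
  stability <- NA_real_
  if (stability_check) {
    m <- max(4L, floor(0.8 * length(sample_ids)))
    changed <- vapply(seq_len(n_resample), function(r) {
      cols <- sort(sample(seq_along(sample_ids), m))
      sub <- cut2(cols)
      ref <- memb[cols]
      ok <- !is.na(sub) & !is.na(ref)
      if (!any(ok)) return(1)
      # align labels by the best of the two possible matchings
      agree <- max(mean(sub[ok] == ref[ok]), mean((3L - sub[ok]) == ref[ok]))
      1 - agree
    }, numeric(1L))
    stability <- mean(changed)
    if (stability > 0.25)
      warning(sprintf(paste0("unstable two-cluster split: resampling 20%% of ",
                             "samples changes %.0f%% of memberships on average"),
                      100 * stability))
  }
  list(clusterA_ids = a, clusterB_ids = b,
       contrast = data.frame(probe_id = probe_panel, p_contrast = unname(p),
                             stringsAsFactors = FALSE),
       stability = stability)
}

#' Select the top signature panel from a cluster contrast
#'
#' Probes are restricted to a survival-filter group tag (by default the
#' proliferation-linked `up_positive` group), ordered by ascending
#' contrast p (ties to the smaller probe id) and the first `n_top` are
#' returned.
#'
#' @param contrast the `contrast` data.frame of
#'   [two_cluster_contrast()].
#' @param group_tags named character vector probe_id -> group tag (from
#'   [survival_filter()]); NULL disables the tag filter.
#' @param n_top panel size (default 10); when fewer probes qualify, all
#'   are returned with a warning.
#' @param group_filter tag to keep (default "up_positive").
#' @return character vector of probe ids.
#' @export
select_top_panel <- function(contrast, group_tags = NULL, n_top = 10L,
                             group_filter = "up_positive") {
  df <- contrast
  if (!is.null(group_tags))
    df <- df[!is.na(group_tags[df$probe_id]) &
               group_tags[df$probe_id] == group_filter, , drop = FALSE]
  df <- df[order(df$p_contrast, df$probe_id, method = "radix"), , drop = FALSE]
  if (nrow(df) < n_top) {
    warning(sprintf("only %d probe(s) qualify (requested %d); returning all",
                    nrow(df), n_top))
    return(df$probe_id)
  }
  df$probe_id[seq_len(n_top)]
}

#' Order samples by their average expression rank over a panel
#'
#' For each probe the samples are mid-ranked (ties share the average
#' rank); each sample's score is the mean of its ranks across the
#' panel. Samples are returned sorted from communally lowest to highest
#' expression, ties broken by sample id.
#'
#' @param cohort an [expression_cohort()].
#' @param sample_ids samples to order.
#' @param panel non-empty probe id vector.
#' @return data.frame (sample_id, mean_rank) sorted ascending.
#' @export
average_rank_order <- function(cohort, sample_ids, panel) {
  stopifnot(length(panel) >= 1L)
  X <- cohort$values[panel, sample_ids, drop = FALSE]
  ranks <- t(apply(X, 1L, rank))               # mid-ranks per probe
  if (length(panel) == 1L) ranks <- matrix(ranks, nrow = 1L)
  mr <- colMeans(ranks)
  out <- data.frame(sample_id = sample_ids, mean_rank = unname(mr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_rank, out$sample_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split rank-ordered samples into equal-size quantile groups
#'
#' Group sizes are `ceiling(N/n)` for the first `N mod n` groups and
#' `floor(N/n)` for the rest, so sizes differ by at most one and the
#' lowest-rank samples land in Q1 (e.g. 629 samples -> 158, 157, 157,
#' 157).
#'
#' @param ordered a data.frame from [average_rank_order()] (or any
#'   data.frame with `sample_id` in rank order).
#' @param n_groups number of quantile groups (default 4).
#' @return a `quantile_assignment` data.frame (sample_id, quantile
#'   factor Q1..Qn, mean_rank when available, method).
#' @export
quantile_split <- function(ordered, n_groups = 4L) {
  ids <- if (is.data.frame(ordered)) ordered$sample_id else ordered
  N <- length(ids)
  if (N < n_groups) stop("fewer samples than groups")
  base <- N %/% n_groups
  sizes <- base + as.integer(seq_len(n_groups) <= N %% n_groups)
  q <- factor(rep(paste0("Q", seq_len(n_groups)), sizes),
              levels = paste0("Q", seq_len(n_groups)))
  out <- data.frame(sample_id = ids, quantile = q, stringsAsFactors = FALSE)
  if (is.data.frame(ordered) && !is.null(ordered$mean_rank))
    out$mean_rank <- ordered$mean_rank
  out$method <- "average_rank"
  class(out) <- c("quantile_assignment", "data.frame")
  out
}

#' Per-quantile centroids over the signature panel
#'
#' Mean log2 expression of each quantile group over the panel, in
#' Q1..Qn order; the resulting `centroid_model` transfers the
#' stratification to a second cohort via [assign_by_centroid()].
#'
#' @param cohort an [expression_cohort()].
#' @param assignment a `quantile_assignment`.
#' @param panel probe panel of the signature.
#' @return a `centroid_model` with groups Q1..Qn.
#' @export
quantile_centroids <- function(cohort, assignment, panel) {
  groups <- split(assignment$sample_id, assignment$quantile)
  build_centroids(cohort, groups, panel)
}

#' Assign samples to quantile groups by nearest centroid
#' @param cohort an [expression_cohort()].
#' @param sample_ids samples to assign.
#' @param model a `centroid_model` with groups Q1..Qn.
#' @return a `quantile_assignment` data.frame with method "centroid".
#' @export
quantile_assign_by_centroid <- function(cohort, sample_ids, model) {
  grp <- assign_by_centroid(cohort$values[rownames(model), sample_ids,
                                          drop = FALSE], model)
  out <- data.frame(sample_id = sample_ids,
                    quantile = factor(grp, levels = colnames(model)),
                    method = "centroid", stringsAsFactors = FALSE)
  class(out) <- c("quantile_assignment", "data.frame")
  out
}

#' Kaplan-Meier comparison of survival across groups
#'
#' Fits per-group Kaplan-Meier curves, reads off the survival
#' probability with Greenwood 95% confidence limits at a horizon, and
#' tests the overall stratification with a K-group log-rank test.
#'
#' @param groups named vector/factor: sample id -> group.
#' @param survival_time,event named vectors over the same sample ids.
#' @param horizon_days evaluation horizon (default 3650, ten years).
#' @return a `survival_comparison` list: `fit` (survfit), `at_horizon`
#'   (data.frame group, n, survival, lower, upper), `logrank_p`,
#'   `logrank_chisq`.
#' @export
compare_survival <- function(groups, survival_time, event,
                             horizon_days = 3650) {
  ids <- names(groups)
  if (is.null(ids)) stop("`groups` must be named by sample id")
  st <- survival_time[ids]; ev <- as.logical(event[ids])
  ok <- !is.na(st) & !is.na(ev)
  g <- factor(groups[ok])
  if (any(table(g) == 0L) || nlevels(g) < 2L)
    stop("need >= 2 non-empty groups with survival data")
  st <- st[ok]; ev <- ev[ok]
  if (sum(ev) == 0L) stop("no events in any group")
  srv <- survival::Surv(st, ev)
  fit <- survival::survfit(srv ~ g, conf.type = "log")
  sm <- summary(fit, times = horizon_days, extend = TRUE)
  at <- data.frame(group = sub("^g=", "", as.character(sm$strata)),
                   n = as.vector(table(g)),
                   survival = sm$surv, lower = sm$lower, upper = sm$upper,
                   stringsAsFactors = FALSE)
  if (nlevels(g) >= 2L && length(unique(g)) >= 2L) {
    sd <- survival::survdiff(srv ~ g)
    chisq <- sd$chisq
    p <- stats::pchisq(chisq, df = nlevels(g) - 1L, lower.tail = FALSE)
  } else {
    chisq <- 0; p <- 1
  }
  structure(list(fit = fit, at_horizon = at, logrank_p = p,
                 logrank_chisq = chisq, horizon_days = horizon_days),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("survival_comparison at %.0f days (log-rank p = %.3g):\n",
              x$horizon_days, x$logrank_p))
  print(x$at_horizon, row.names = FALSE)
  invisible(x)
}

#' Plot Kaplan-Meier curves of a survival comparison as SVG
#' @param comparison a `survival_comparison`.
#' @param path output SVG path.
#' @return the path, invisibly.
#' @export
plot_km_svg <- function(comparison, path) {
  grDevices::svg(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  n <- length(comparison$fit$strata)
  cols <- grDevices::hcl.colors(max(n, 2L), "Dark 3")
  plot(comparison$fit, col = cols, lwd = 2, xlab = "days",
       ylab = "survival probability")
  graphics::legend("bottomleft",
                   legend = sub("^g=", "", names(comparison$fit$strata)),
                   col = cols[seq_len(n)], lwd = 2, bty = "n")
  invisible(path)
}
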