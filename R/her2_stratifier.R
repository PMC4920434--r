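#' Discover the co-expression cluster around a seed probe
#'
#' Spearman correlation of every probe against the seed probe across the
#' specified samples; probes with rho strictly greater than `rho_min`
#' form the cluster (the threshold is one-sided: strong anti-correlation
#' does not qualify). Correlation p-values use the t approximation,
#' which tolerates the ties always present in expression data.
#'
#' @param cohort an [expression_cohort()].
#' @param seed_probe probe id of the cluster seed (e.g. the HER2/ERBB2
#'   probe).
#' @param rho_min correlation threshold (default 0.5, strict).
#' @param sample_ids samples over which to correlate (default: all,
#'   tumours and controls).
#' @return a `cluster_discovery` data.frame (probe_id, gene_symbol, rho,
#'   p_value) sorted by descending rho, seed first with rho = 1;
#'   `attr(,"rho_min")` records the threshold.
#' @export
discover_cluster <- function(cohort, seed_probe, rho_min = 0.5,
                             sample_ids = NULL) {
  if (!seed_probe %in% rownames(cohort$values))
    stop("unknown seed probe: ", seed_probe)
  if (is.null(sample_ids)) sample_ids <- colnames(cohort$values)
  if (length(sample_ids) < 10L) stop("need at least 10 samples")
  seed_v <- cohort$values[seed_probe, sample_ids]
  if (stats::sd(seed_v) == 0) stop("seed probe has constant values")
  X <- t(cohort$values[, sample_ids, drop = FALSE])
  rho <- suppressWarnings(as.numeric(stats::cor(X, seed_v, method = "spearman")))
  names(rho) <- colnames(X)
  member <- which(rho > rho_min)
  nS <- length(sample_ids)
  pval <- vapply(member, function(j) {
    r <- rho[j]
    if (abs(r) >= 1) return(0)
    tt <- r * sqrt((nS - 2) / (1 - r^2))
    2 * stats::pt(abs(tt), nS - 2, lower.tail = FALSE)
  }, numeric(1L))
  out <- data.frame(probe_id = names(rho)[member],
                    gene_symbol = cohort$probe_meta$gene_symbol[member],
                    rho = rho[member], p_value = pval,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rho, out$probe_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed_probe") <- seed_probe
  attr(out, "rho_min") <- rho_min
  class(out) <- c("cluster_discovery", "data.frame")
  out
}

#' Build per-group mean-expression centroids over a probe panel
#'
#' @param cohort an [expression_cohort()].
#' @param group_assignments named list: group name -> non-empty sample
#'   id vector. The list order fixes the tie-break order of
#'   [assign_by_centroid()].
#' @param panel ordered probe ids of the centroid panel.
#' @return a `centroid_model`: panel x group matrix of mean log2 values,
#'   with the group order recorded.
#' @export
build_centroids <- function(cohort, group_assignments, panel) {
  miss <- setdiff(panel, rownames(cohort$values))
  if (length(miss)) stop("unknown probe id(s): ", paste(miss, collapse = ", "))
  if (!length(group_assignments) || is.null(names(group_assignments)))
    stop("group_assignments must be a named list")
  cen <- vapply(group_assignments, function(ids) {
    if (!length(ids)) stop("empty group in group_assignments")
    miss <- setdiff(ids, colnames(cohort$values))
    if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
    rowMeans(cohort$values[panel, ids, drop = FALSE])
  }, numeric(length(panel)))
  cen <- matrix(cen, nrow = length(panel),
                dimnames = list(panel, names(group_assignments)))
  structure(cen, class = c("centroid_model", "matrix"))
}

#' Assign a sample to the nearest centroid
#'
#' Euclidean distance over the model's probe panel; ties go to the first
#' group in the model's declared order.
#'
#' @param sample_vector named numeric vector (or probes x samples
#'   matrix) aligned to the model panel.
#' @param model a `centroid_model`.
#' @return character vector of group names (one per sample).
#' @export
assign_by_centroid <- function(sample_vector, model) {
  panel <- rownames(model)
  if (is.matrix(sample_vector)) {
    X <- sample_vector[panel, , drop = FALSE]
  } else {
    if (!is.null(names(sample_vector))) sample_vector <- sample_vector[panel]
    if (length(sample_vector) != length(panel))
      stop("sample vector not aligned to the model panel")
    X <- matrix(sample_vector, ncol = 1L, dimnames = list(panel, NULL))
  }
  if (anyNA(X)) stop("missing value(s) in sample vector; impute or drop first")
  groups <- colnames(model)
  d2 <- vapply(groups, function(g) colSums((X - model[, g])^2),
               numeric(ncol(X)))
  d2 <- matrix(d2, ncol = length(groups), dimnames = list(colnames(X), groups))
  groups[apply(d2, 1L, which.min)]   # which.min takes the first on ties
}

#' Split luminal tumours into HER2-amplified and ordinary luminal
#'
#' Discovers the seed probe's co-expression cluster on the cohort,
#' builds two centroids over the cluster panel (mean expression of the
#' luminal reference group and of the HER2-enriched reference group) and
#' assigns every luminal sample to the nearest centroid. Samples closer
#' to the HER2-enriched centroid are called `her2_amplified_luminal`,
#' the rest `ordinary_luminal` (declared first, so exact ties stay
#' ordinary).
#'
#' @param cohort an [expression_cohort()].
#' @param luminal_ids sample ids of the luminal tumours to stratify.
#' @param her2_enriched_ids reference HER2-enriched samples.
#' @param seed_probe cluster seed probe id.
#' @param rho_min cluster correlation threshold (default 0.5).
#' @param cor_samples samples used for cluster discovery (default: all).
#' @param model optional frozen `centroid_model` (with groups
#'   `ordinary_luminal`, `her2_amplified_luminal`) for transfer to a
#'   second cohort; when supplied, discovery and centroid building are
#'   skipped.
#' @return a `her2_stratification` list: `assignment` (data.frame
#'   sample_id, group), `fraction_amplified`, `cluster`
#'   (the discovery table) and `model` (the centroid model).
#' @export
stratify_luminal <- function(cohort, luminal_ids, her2_enriched_ids = NULL,
                             seed_probe = NULL, rho_min = 0.5,
                             cor_samples = NULL, model = NULL) {
  if (!length(luminal_ids)) stop("luminal_ids must be non-empty")
  cluster <- NULL
  if (is.null(model)) {
    if (is.null(seed_probe) || !length(her2_enriched_ids))
      stop("need seed_probe and her2_enriched_ids (or a frozen model)")
    cluster <- discover_cluster(cohort, seed_probe, rho_min = rho_min,
                                sample_ids = cor_samples)
    panel <- cluster$probe_id
    model <- build_centroids(
      cohort,
      list(ordinary_luminal = luminal_ids,
           her2_amplified_luminal = her2_enriched_ids),
      panel)
  }
  grp <- assign_by_centroid(cohort$values[rownames(model), luminal_ids,
                                          drop = FALSE], model)
  assignment <- data.frame(sample_id = luminal_ids, group = grp,
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment,
                 fraction_amplified = mean(grp == "her2_amplified_luminal"),
                 cluster = cluster, model = model),
            class = "her2_stratification")
}

#' @export
print.her2_stratification <- function(x, ...) {
  cat(sprintf("her2_stratification: %d luminal samples, %.1f%% HER2-amplified\n",
              nrow(x$assignment), 100 * x$fraction_amplified))
  invisible(x)
}

#' Serialise a centroid model as TSV (panel row per probe, one column
#' per group)
#' @param model a `centroid_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_centroid_model <- function(model, path) {
  df <- data.frame(probe_id = rownames(model), as.data.frame(unclass(model)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a centroid model written by [write_centroid_model()]
#' @param path input TSV.
#' @return a `centroid_model`.
#' @export
read_centroid_model <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  structure(m, class = c("centroid_model", "matrix"))
}
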