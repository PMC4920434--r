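#' Expression cohort container
#'
#' An `expression_cohort` bundles a probes x samples matrix of log2
#' intensities with per-probe genomic annotation and per-sample clinical
#' annotation. It is the substrate of every stage of the stratification
#' pipeline. Genome coordinates are held 0-based half-open throughout the
#' package.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#'   Dimnames are taken as probe and sample identifiers.
#' @param probe_meta data.frame with one row per probe: columns
#'   `probe_id`, `gene_symbol`, `chromosome`, `cytoband`, `start_bp`,
#'   `end_bp`.
#' @param sample_meta data.frame with one row per sample: columns
#'   `sample_id`, `is_control` (logical), `subtype_label` (one of
#'   `lumA`, `lumB`, `her2e`, `basal`, `control`, `unknown`),
#'   `survival_time` (days, NA allowed), `event` (logical/0-1, NA
#'   allowed); further clinical columns are carried along untouched.
#' @return an object of class `expression_cohort`.
#' @export
expression_cohort <- function(values, probe_meta, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  probe_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("`values` must carry probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  probe_meta <- as.data.frame(probe_meta, stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (!setequal(probe_meta$probe_id, probe_ids))
    stop("probe_meta does not match the probe ids of the matrix")
  if (!setequal(sample_meta$sample_id, sample_ids))
    stop("sample_meta does not match the sample ids of the matrix: missing ",
         paste(setdiff(sample_ids, sample_meta$sample_id), collapse = ", "))
  probe_meta <- probe_meta[match(probe_ids, probe_meta$probe_id), , drop = FALSE]
  sample_meta <- sample_meta[match(sample_ids, sample_meta$sample_id), , drop = FALSE]
  rownames(probe_meta) <- NULL
  rownames(sample_meta) <- NULL
  if (!is.logical(sample_meta$is_control))
    sample_meta$is_control <- as.logical(sample_meta$is_control)
  st <- sample_meta$survival_time
  if (!is.null(st) && any(!is.na(st) & st < 0))
    stop("survival_time must be >= 0 where present")
  structure(
    list(values = values, probe_meta = probe_meta, sample_meta = sample_meta),
    class = "expression_cohort"
  )
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression_cohort: %d probes x %d samples (%d controls, %d tumours)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_meta$is_control), sum(!x$sample_meta$is_control)))
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$values)

#' Sample ids of the tumour / control compartments
#' @param cohort an `expression_cohort`.
#' @return character vector of sample ids.
#' @export
tumour_ids <- function(cohort) {
  cohort$sample_meta$sample_id[!cohort$sample_meta$is_control]
}

#' @rdname tumour_ids
#' @export
control_ids <- function(cohort) {
  cohort$sample_meta$sample_id[cohort$sample_meta$is_control]
}

#' Restrict a cohort to a subset of probes and/or samples
#' @param cohort an `expression_cohort`.
#' @param probes,samples identifiers to keep (default: all).
#' @return an `expression_cohort`.
#' @export
subset_cohort <- function(cohort, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- rownames(cohort$values)
  if (is.null(samples)) samples <- colnames(cohort$values)
  miss <- setdiff(probes, rownames(cohort$values))
  if (length(miss)) stop("unknown probe id(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(samples, colnames(cohort$values))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  expression_cohort(
    cohort$values[probes, samples, drop = FALSE],
    cohort$probe_meta[match(probes, cohort$probe_meta$probe_id), , drop = FALSE],
    cohort$sample_meta[match(samples, cohort$sample_meta$sample_id), , drop = FALSE]
  )
}
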