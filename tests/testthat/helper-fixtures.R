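# Fixtures are built in code; nothing is read from disk except what the
# tests themselves write to tempdir().

# A small hand-built cohort: 6 probes x 8 samples (5 tumours, 3 controls)
tiny_cohort <- function() {
  set.seed(99)
  v <- matrix(round(rnorm(48, 7, 1), 4), 6, 8,
              dimnames = list(sprintf("P%02d", 1:6), sprintf("S%02d", 1:8)))
  pm <- data.frame(probe_id = rownames(v),
                   gene_symbol = c("A", "B", "C", "D", "E", "F"),
                   chromosome = "chr1", cytoband = "q11",
                   start_bp = seq(0, 5000, by = 1000),
                   end_bp = seq(500, 5500, by = 1000))
  sm <- data.frame(sample_id = colnames(v),
                   is_control = c(rep(FALSE, 5), rep(TRUE, 3)),
                   subtype_label = c(rep("lumA", 3), rep("lumB", 2),
                                     rep("control", 3)),
                   survival_time = c(100, 300, 800, 1500, 2500, NA, NA, NA),
                   event = c(TRUE, TRUE, FALSE, TRUE, FALSE, NA, NA, NA))
  expression_cohort(v, pm, sm)
}

# build an expression_cohort from a bare matrix (minimal annotations)
cohort_from_matrix <- function(v, is_control,
                               survival_time = NULL, event = NULL) {
  pm <- data.frame(probe_id = rownames(v), gene_symbol = rownames(v),
                   chromosome = "chr1", cytoband = "q11",
                   start_bp = 0L, end_bp = 100L)
  sm <- data.frame(sample_id = colnames(v), is_control = is_control,
                   subtype_label = ifelse(is_control, "control", "lumA"),
                   survival_time = if (is.null(survival_time)) NA_real_ else survival_time,
                   event = if (is.null(event)) NA else event)
  expression_cohort(v, pm, sm)
}

# distance matrix from 1-d / 2-d point coordinates with stable ids
dist_fixture <- function(x, ids = NULL) {
  D <- as.matrix(dist(x))
  n <- nrow(D)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  dimnames(D) <- list(ids, ids)
  D
}

# exact one-sided rank-sum p by enumeration of all group assignments
# (independent of stats::wilcox.test); alternative "less": x below y
enum_ranksum_p <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2L, function(idx) sum(r[idx]))
  if (alternative == "less") mean(w_all <= w_obs) else mean(w_all >= w_obs)
}

# null generator configuration: no planted structure at all
null_cohort_config <- function(seed, n_tumour = 150L, n_control = 60L,
                               n_probes = 1000L) {
  cohort_config(n_tumour = n_tumour, n_control = n_control,
                n_probes = n_probes,
                frac_diff_up = 0, frac_diff_down = 0, frac_diff_bimodal = 0,
                frac_her2_amp = 0, n_risk_probes = 0L, hazard_coef = 0,
                seed = seed)
}
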