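#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a luminal breast-cancer training
#' cohort: 680 tumours and 144 controls profiled on a desk-scale array of
#' 2,000 probes, a small fraction of probes with planted tumour-control
#' shifts (up, down, or bimodally dysregulated), a 7-probe co-amplified
#' HER2-locus block present in 8% of tumours, a continuous
#' proliferation-like risk gradient tied to survival hazard, and
#' copy-number gain/loss segments whose per-cytoband frequency increases
#' along the risk gradient.
#'
#' @param n_tumour,n_control,n_probes cohort dimensions.
#' @param frac_diff_up,frac_diff_down,frac_diff_bimodal fractions of
#'   probes with planted tumour-control shifts; must sum to <= 1.
#' @param effect_size_sd planted shift magnitude in control-SD units.
#' @param frac_her2_amp fraction of tumours with the planted HER2-block
#'   amplification.
#' @param her2_block_size number of co-amplified probes in the block.
#' @param n_risk_probes probes expressing the latent risk score. Risk
#'   probes are planted only when `hazard_coef != 0`: the generator
#'   defines "risk structure" as the joint expression-survival link.
#' @param hazard_coef log-hazard increase per risk-score SD.
#' @param censor_rate expected fraction of tumours censored (independent
#'   exponential censoring).
#' @param cna_base_rate,cna_risk_slope per-cytoband gain/loss probability
#'   on the designated risk cytobands: `cna_base_rate +
#'   cna_risk_slope * rank01(risk)`.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_tumour = 680L, n_control = 144L, n_probes = 2000L,
                          frac_diff_up = 0.05, frac_diff_down = 0.05,
                          frac_diff_bimodal = 0.02, effect_size_sd = 3,
                          frac_her2_amp = 0.08, her2_block_size = 7L,
                          n_risk_probes = 50L, hazard_coef = 0.7,
                          censor_rate = 0.3,
                          cna_base_rate = 0.15, cna_risk_slope = 0.5,
                          seed = 1L) {
  cfg <- list(n_tumour = as.integer(n_tumour), n_control = as.integer(n_control),
              n_probes = as.integer(n_probes),
              frac_diff_up = frac_diff_up, frac_diff_down = frac_diff_down,
              frac_diff_bimodal = frac_diff_bimodal,
              effect_size_sd = effect_size_sd,
              frac_her2_amp = frac_her2_amp,
              her2_block_size = as.integer(her2_block_size),
              n_risk_probes = as.integer(n_risk_probes),
              hazard_coef = hazard_coef, censor_rate = censor_rate,
              cna_base_rate = cna_base_rate, cna_risk_slope = cna_risk_slope,
              seed = as.integer(seed))
  fr <- c(cfg$frac_diff_up, cfg$frac_diff_down, cfg$frac_diff_bimodal,
          cfg$frac_her2_amp, cfg$censor_rate, cfg$cna_base_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$frac_diff_up + cfg$frac_diff_down + cfg$frac_diff_bimodal > 1)
    stop("frac_diff_* must sum to <= 1")
  if (any(c(cfg$n_tumour, cfg$n_control, cfg$n_probes) <= 0))
    stop("counts must be positive")
  if (cfg$cna_risk_slope < 0) stop("cna_risk_slope must be >= 0")
  class(cfg) <- "cohort_config"
  cfg
}

# Toy genome: 6 chromosomes x 12 bands of 2 Mb. chr17 q12 hosts the HER2
# block; gain bands on chr8/17/20 and loss bands on chr11 carry the
# risk-linked CNA events; chr1 q21 gain and chr16 q22 loss are constant.
.toy_bands <- c("p15", "p14", "p13", "p12", "p11",
                "q11", "q12", "q13", "q21", "q22", "q23", "q24")
.toy_chroms <- c("chr1", "chr8", "chr11", "chr16", "chr17", "chr20")
.band_mb <- 2e6

toy_cytobands <- function() {
  df <- expand.grid(band_name = .toy_bands, chromosome = .toy_chroms,
                    stringsAsFactors = FALSE)[, 2:1]
  df$start_bp <- rep((seq_along(.toy_bands) - 1L) * .band_mb, length(.toy_chroms))
  df$end_bp <- df$start_bp + .band_mb
  cytoband_map(df)
}

.band_key <- function(chromosome, band_name) paste0(chromosome, band_name)
.gain_bands <- c("chr8q21", "chr8q22", "chr8q23", "chr8q24",
                 "chr17q21", "chr17q22", "chr20q13")
.loss_bands <- c("chr11q23", "chr11q24")
.const_gain_band <- "chr1q21"
.const_loss_band <- "chr16q22"
.her2_band <- "chr17q12"

#' Generate a synthetic cohort with ground truth
#'
#' Control expression is Gaussian per probe (means around 7, residual SD
#' 0.5 on the log2 scale). Planted differential probes are shifted by
#' `effect_size_sd` control-SDs in tumours (up, down, or up in a random
#' half of tumours and down in the other half). The HER2 block is shifted
#' by +2 log2 units in the planted tumours with a shared latent factor so
#' the block co-correlates. Risk probes follow a monotone affine function
#' of the standardised latent risk score; survival is exponential with
#' log-linear hazard in the risk score and independent exponential
#' censoring. Copy-number gain/loss segments are dropped on designated
#' cytobands with probability increasing in the risk rank, with
#' `seg_mean` feeding back into the expression of co-located risk probes.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `cohort` ([expression_cohort()]),
#'   `segments` (`cna_segments`), `cytobands` (`cytoband_map`), `truth`
#'   (ground-truth ids and scores) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  np <- config$n_probes; nt <- config$n_tumour; nc <- config$n_control
  n <- nt + nc
  cyto <- toy_cytobands()
  band_keys <- .band_key(cyto$chromosome, cyto$band_name)

  probe_ids <- sprintf("PRB%05d", seq_len(np))
  gene_symbols <- sprintf("GENE%05d", seq_len(np))
  nb <- config$her2_block_size
  if (np < nb + config$n_risk_probes + 10L)
    stop("n_probes too small for the planted structures")
  her2_idx <- seq_len(nb)
  her2_names <- c("ERBB2", "PGAP3", "GRB7", "STARD3", "ORMDL3", "MIEN1", "PNMT",
                  sprintf("HER2BLK%02d", seq_len(max(0L, nb - 7L))))
  gene_symbols[her2_idx] <- her2_names[seq_len(nb)]

  # probe placement: HER2 block on chr17q12, risk probes round-robin on
  # the designated gain bands, the rest spread over the whole toy genome
  probe_band <- character(np)
  probe_band[her2_idx] <- .her2_band
  plant_risk <- config$hazard_coef != 0 && config$n_risk_probes > 0L
  risk_idx <- if (config$n_risk_probes > 0L) nb + seq_len(config$n_risk_probes) else integer(0)
  probe_band[risk_idx] <- rep_len(.gain_bands, length(risk_idx))
  rest <- setdiff(seq_len(np), c(her2_idx, risk_idx))
  probe_band[rest] <- rep_len(band_keys, length(rest))
  bi <- match(probe_band, band_keys)
  width <- 2000L
  start_bp <- cyto$start_bp[bi] +
    sapply(seq_len(np), function(i) sample.int(.band_mb - width, 1L))
  probe_meta <- data.frame(
    probe_id = probe_ids, gene_symbol = gene_symbols,
    chromosome = cyto$chromosome[bi], cytoband = cyto$band_name[bi],
    start_bp = start_bp, end_bp = start_bp + width,
    stringsAsFactors = FALSE)

  sample_ids <- c(sprintf("T%04d", seq_len(nt)), sprintf("C%04d", seq_len(nc)))
  is_control <- c(rep(FALSE, nt), rep(TRUE, nc))
  t_ids <- sample_ids[!is_control]

  # baseline expression
  mu <- stats::rnorm(np, 7, 0.5)
  sd0 <- 0.5
  values <- matrix(stats::rnorm(np * n, 0, sd0), np, n,
                   dimnames = list(probe_ids, sample_ids)) + mu

  # planted differential probes (disjoint from HER2 block and risk probes)
  pool <- setdiff(seq_len(np), c(her2_idx, risk_idx))
  n_up <- round(config$frac_diff_up * np)
  n_dn <- round(config$frac_diff_down * np)
  n_bi <- round(config$frac_diff_bimodal * np)
  picked <- sample(pool, n_up + n_dn + n_bi)
  up_idx <- picked[seq_len(n_up)]
  dn_idx <- picked[n_up + seq_len(n_dn)]
  bi_idx <- picked[n_up + n_dn + seq_len(n_bi)]
  eff <- config$effect_size_sd * sd0
  tcol <- which(!is_control)
  values[up_idx, tcol] <- values[up_idx, tcol] + eff
  values[dn_idx, tcol] <- values[dn_idx, tcol] - eff
  for (j in bi_idx) {
    half <- sample(tcol, floor(nt / 2))
    values[j, half] <- values[j, half] + eff
    values[j, setdiff(tcol, half)] <- values[j, setdiff(tcol, half)] - eff
  }

  # HER2 block: baseline co-regulation via a cohort-wide shared latent
  # factor (17q12 genes are co-expressed in every sample; their residual
  # noise is tighter than the array-wide 0.5), plus a +2 log2
  # amplification shift in the planted tumours
  her2_factor <- stats::rnorm(n, 0, 0.4)
  values[her2_idx, ] <- mu[her2_idx] +
    matrix(stats::rnorm(nb * n, 0, 0.35), nb, n) + rep(her2_factor, each = nb)
  n_amp <- round(config$frac_her2_amp * nt)
  amp_col <- sort(sample(tcol, n_amp))
  if (n_amp > 0L)
    values[her2_idx, amp_col] <- values[her2_idx, amp_col] + 2

  # latent risk score (standardised over tumours)
  risk <- as.numeric(scale(stats::rnorm(nt)))
  names(risk) <- t_ids
  if (plant_risk)
    values[risk_idx, tcol] <- values[risk_idx, tcol] +
      rep(1 + 0.8 * risk, each = length(risk_idx))

  # survival: exponential, log-linear hazard; independent censoring
  lambda0 <- -log(0.75) / 3650          # 75% ten-year survival at risk 0
  lam <- lambda0 * exp(config$hazard_coef * risk)
  t_event <- stats::rexp(nt, lam)
  surv_time <- t_event
  event <- rep(TRUE, nt)
  if (config$censor_rate > 0) {
    lam_c <- lambda0 * config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(nt, lam_c)
    surv_time <- pmin(t_event, t_cens)
    event <- t_event <= t_cens
  }

  # subtype labels: the top risk third is labelled lumB
  lumB <- rank(risk, ties.method = "first") > ceiling(2 * nt / 3)
  subtype <- c(ifelse(lumB, "lumB", "lumA"), rep("control", nc))
  sample_meta <- data.frame(
    sample_id = sample_ids, is_control = is_control, subtype_label = subtype,
    survival_time = c(round(surv_time, 3), rep(NA_real_, nc)),
    event = c(event, rep(NA, nc)),
    stringsAsFactors = FALSE)

  # copy-number segments on the toy genome
  rank01 <- if (nt > 1L) (rank(risk, ties.method = "first") - 1) / (nt - 1) else rep(0, nt)
  seg <- list()
  band_row <- function(key) which(band_keys == key)
  add_seg <- function(s_id, key, state, mean) {
    r <- band_row(key)
    data.frame(sample_id = s_id, chromosome = cyto$chromosome[r],
               start_bp = cyto$start_bp[r], end_bp = cyto$end_bp[r],
               state = state, seg_mean = mean, stringsAsFactors = FALSE)
  }
  events <- list()
  for (i in seq_len(nt)) {
    sid <- t_ids[i]
    p_i <- min(1, config$cna_base_rate + config$cna_risk_slope * rank01[i])
    for (b in .gain_bands) if (stats::runif(1) < p_i)
      seg[[length(seg) + 1L]] <- add_seg(sid, b, "gain",
                                         round(0.35 + abs(stats::rnorm(1, 0, 0.12)), 4))
    for (b in .loss_bands) if (stats::runif(1) < p_i)
      seg[[length(seg) + 1L]] <- add_seg(sid, b, "heterozygous deletion",
                                         round(-0.35 - abs(stats::rnorm(1, 0, 0.12)), 4))
    if (stats::runif(1) < 0.6)
      seg[[length(seg) + 1L]] <- add_seg(sid, .const_gain_band, "gain",
                                         round(0.3 + abs(stats::rnorm(1, 0, 0.1)), 4))
    if (stats::runif(1) < 0.4)
      seg[[length(seg) + 1L]] <- add_seg(sid, .const_loss_band, "heterozygous deletion",
                                         round(-0.3 - abs(stats::rnorm(1, 0, 0.1)), 4))
    seg[[length(seg) + 1L]] <- add_seg(sid, "chr1p13", "neutral",
                                       round(stats::rnorm(1, 0, 0.03), 4))
  }
  if (n_amp > 0L) for (sid in sample_ids[amp_col])
    seg[[length(seg) + 1L]] <- add_seg(sid, .her2_band, "amplification",
                                       round(0.8 + abs(stats::rnorm(1, 0, 0.15)), 4))
  segments <- cna_segments(do.call(rbind, seg))

  # gains feed back into the expression of co-located risk probes
  if (plant_risk) {
    gains <- segments[segments$state %in% c("gain", "amplification"), , drop = FALSE]
    gkey <- .band_key(gains$chromosome,
                      lookup_cytoband(cyto, gains$chromosome, gains$start_bp))
    for (j in risk_idx) {
      hit <- gkey == probe_band[j] & gains$sample_id %in% t_ids
      if (any(hit))
        values[j, gains$sample_id[hit]] <- values[j, gains$sample_id[hit]] +
          1.2 * gains$seg_mean[hit]
    }
  }

  cohort <- expression_cohort(values, probe_meta, sample_meta)
  truth <- list(
    probe_ids = probe_ids, sample_ids = sample_ids,
    planted_diff_probes = data.frame(
      probe_id = probe_ids[c(up_idx, dn_idx, bi_idx)],
      mode = rep(c("up", "down", "bimodal"), c(n_up, n_dn, n_bi)),
      stringsAsFactors = FALSE),
    planted_her2_samples = sample_ids[amp_col],
    planted_her2_probes = probe_ids[her2_idx],
    planted_risk_probes = if (plant_risk) probe_ids[risk_idx] else character(0),
    risk_score = risk,
    seed = config$seed)
  list(cohort = cohort, segments = segments, cytobands = cyto,
       truth = truth, config = config)
}

#' Confusion summary of predictions against planted ground truth
#'
#' @param truth the `truth` element of [generate_cohort()] output.
#' @param predictions named list with any of `diff_probes`,
#'   `her2_samples`, `her2_probes`, `risk_probes`: predicted identifier
#'   vectors.
#' @return data.frame with one row per prediction class: number planted,
#'   number predicted, true positives, precision (NA when nothing was
#'   predicted) and recall.
#' @export
truth_report <- function(truth, predictions) {
  classes <- list(
    diff_probes = list(truth = truth$planted_diff_probes$probe_id, pool = truth$probe_ids),
    her2_samples = list(truth = truth$planted_her2_samples, pool = truth$sample_ids),
    her2_probes = list(truth = truth$planted_her2_probes, pool = truth$probe_ids),
    risk_probes = list(truth = truth$planted_risk_probes, pool = truth$probe_ids))
  out <- lapply(names(predictions), function(cl) {
    if (is.null(classes[[cl]])) stop("unknown prediction class: ", cl)
    pred <- predictions[[cl]]
    unknown <- setdiff(pred, classes[[cl]]$pool)
    if (length(unknown))
      stop("unknown id(s) in ", cl, ": ", paste(utils::head(unknown, 5), collapse = ", "))
    tr <- classes[[cl]]$truth
    tp <- length(intersect(pred, tr))
    data.frame(class = cl, n_truth = length(tr), n_pred = length(pred), tp = tp,
               precision = if (length(pred)) tp / length(pred) else NA_real_,
               recall = if (length(tr)) tp / length(tr) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
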