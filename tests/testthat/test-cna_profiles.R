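toy_segments <- function(df) {
  df$seg_mean <- if (is.null(df$seg_mean)) 0.5 else df$seg_mean
  cna_segments(df)
}

test_that("state classification follows the two-category rule", {
  seg <- toy_segments(data.frame(
    sample_id = "S1", chromosome = "chr1",
    start_bp = c(0, 10, 20, 30, 40), end_bp = c(5, 15, 25, 35, 45),
    state = c("amplification", "gain", "neutral",
              "heterozygous deletion", "homozygous deletion"),
    seg_mean = c(1, 0.4, 0, -0.4, -1.5)))
  got <- classify_states(seg)
  expect_equal(got$category, c("gain", "gain", "none", "loss", "loss"))
})

# a 10 kb toy genome in 10 bands of 1 kb each
toy_genome <- function() cytoband_map(data.frame(
  chromosome = "chr1", start_bp = seq(0, 9000, 1000),
  end_bp = seq(1000, 10000, 1000), band_name = paste0("b", 1:10)))

test_that("cytoband occurrence counts samples once per band and category", {
  cb <- toy_genome()
  # one gain covering all of band b1, subgroup of size 2 -> rate 0.5
  seg <- toy_segments(data.frame(sample_id = "S1", chromosome = "chr1",
                                 start_bp = 0, end_bp = 1000, state = "gain"))
  sub <- c(S1 = "grp", S2 = "grp")
  prof <- cytoband_occurrence(seg, cb, sub)
  expect_equal(prof$rate[prof$band_name == "b1" & prof$category == "gain"], 0.5)
  expect_equal(sum(prof$count), 1L)

  # a segment spanning two bands is counted on both
  seg2 <- toy_segments(data.frame(sample_id = "S1", chromosome = "chr1",
                                  start_bp = 900, end_bp = 1100, state = "gain"))
  prof2 <- cytoband_occurrence(seg2, cb, sub)
  hit <- prof2[prof2$count > 0, ]
  expect_setequal(hit$band_name, c("b1", "b2"))

  # two overlapping gains of one sample on one band still count once
  seg3 <- toy_segments(data.frame(sample_id = "S1", chromosome = "chr1",
                                  start_bp = c(0, 500), end_bp = c(600, 900),
                                  state = "gain"))
  prof3 <- cytoband_occurrence(seg3, cb, sub)
  expect_equal(max(prof3$count), 1L)

  # unknown chromosome: warning, segment skipped
  seg4 <- toy_segments(data.frame(sample_id = "S1", chromosome = "chrZ",
                                  start_bp = 0, end_bp = 100, state = "gain"))
  expect_warning(prof4 <- cytoband_occurrence(seg4, cb, sub), "chrZ")
  expect_equal(sum(prof4$count), 0L)
})

test_that("cytoband occurrence equals a per-base brute-force oracle on the
           toy genome and is invariant to splitting segments", {
  set.seed(61)
  cb <- toy_genome()
  n_seg <- 50
  samples <- sprintf("S%02d", 1:6)
  start <- sample(0:9900, n_seg)
  len <- sample(50:3000, n_seg, replace = TRUE)
  seg <- toy_segments(data.frame(
    sample_id = sample(samples, n_seg, replace = TRUE),
    chromosome = "chr1", start_bp = start,
    end_bp = pmin(start + len, 10000),
    state = sample(c("gain", "amplification", "heterozygous deletion",
                     "homozygous deletion", "neutral"), n_seg, replace = TRUE)))
  sub <- setNames(rep(c("g1", "g2"), each = 3), samples)
  prof <- cytoband_occurrence(seg, cb, sub)

  # per-base oracle: genome as a vector of base flags per sample/category
  oracle_rate <- function(band_row, grp, cat) {
    b <- cb[band_row, ]
    cls <- classify_states(seg)
    covered <- vapply(samples[sub == grp], function(s) {
      sc <- cls[cls$sample_id == s & cls$category == cat, , drop = FALSE]
      if (!nrow(sc)) return(FALSE)
      base <- rep(FALSE, 10000)
      for (i in seq_len(nrow(sc)))
        base[(sc$start_bp[i] + 1):sc$end_bp[i]] <- TRUE
      any(base[(b$start_bp + 1):b$end_bp])
    }, logical(1))
    mean(covered)
  }
  for (i in sample(nrow(prof), 20)) {
    br <- which(cb$band_name == prof$band_name[i])
    expect_equal(prof$rate[i],
                 oracle_rate(br, prof$subgroup[i], prof$category[i]),
                 info = paste(prof$band_name[i], prof$subgroup[i],
                              prof$category[i]))
  }

  # splitting any segment into two adjacent halves changes nothing
  seg_split <- seg[rep(seq_len(nrow(seg)), each = 2), ]
  mid <- (seg$start_bp + seg$end_bp) %/% 2
  odd <- seq(1, nrow(seg_split), 2)
  seg_split$end_bp[odd] <- mid
  seg_split$start_bp[odd + 1] <- mid
  seg_split <- seg_split[seg_split$end_bp > seg_split$start_bp, ]
  prof_split <- cytoband_occurrence(cna_segments(seg_split), cb, sub)
  expect_equal(prof_split$rate, prof$rate)
})

test_that("per-band proportion tests: trivials and the 2x2 textbook formula", {
  mk_prof <- function(counts, n) {
    p <- data.frame(chromosome = "chr1", band_name = "b1",
                    subgroup = paste0("Q", seq_along(counts)),
                    category = "gain", count = counts, n = n)
    p$rate <- p$count / p$n
    class(p) <- c("cytoband_profile", "data.frame")
    p
  }
  # exactly proportional counts: statistic 0, p = 1
  t0 <- proportion_test_per_band(mk_prof(c(10, 10, 10, 10), 50))
  expect_equal(t0$p_value, 1, tolerance = 1e-12)

  # 2-subgroup case equals the textbook 2x2 chi-square (no correction)
  t2 <- proportion_test_per_band(mk_prof(c(12, 30), c(50, 60)))
  m <- rbind(c(12, 38), c(30, 30))
  N <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / N
  chi <- sum((m - expected)^2 / expected)
  expect_equal(t2$p_value, pchisq(chi, df = 1, lower.tail = FALSE))
  expect_equal(t2$p_value, prop.test(c(12, 30), c(50, 60),
                                     correct = FALSE)$p.value)

  # degenerate bands (no events anywhere / everyone affected) are flagged
  td <- proportion_test_per_band(mk_prof(c(0, 0, 0, 0), 50))
  expect_true(td$degenerate)
  expect_equal(td$p_value, 1)
  ta <- proportion_test_per_band(mk_prof(c(50, 50, 50, 50), 50))
  expect_true(ta$degenerate)
})

test_that("proportion test detects monotone planted rates", {
  set.seed(62)
  hits <- 0
  for (r in 1:20) {
    counts <- rbinom(4, 150, c(0.1, 0.2, 0.3, 0.4))
    p <- data.frame(chromosome = "chr1", band_name = "b1",
                    subgroup = paste0("Q", 1:4), category = "gain",
                    count = counts, n = 150)
    p$rate <- p$count / p$n
    class(p) <- c("cytoband_profile", "data.frame")
    if (proportion_test_per_band(p)$p_value < 1e-4) hits <- hits + 1
  }
  expect_gte(hits, 19)   # >= 95% of replicates
})

test_that("common regions match intersections and a per-base oracle", {
  sub2 <- c(S1 = "g", S2 = "g")
  # identical segments in both samples: one region, rate 1
  seg <- toy_segments(data.frame(sample_id = c("S1", "S2"), chromosome = "chr1",
                                 start_bp = 100, end_bp = 300, state = "gain"))
  cr <- common_regions(seg, sub2, "gain", min_rate = 0.5)
  expect_equal(nrow(cr), 1L)
  expect_equal(c(cr$start_bp, cr$end_bp), c(100, 300))
  expect_equal(cr$rate_g, 1)

  # staggered [0,100) and [50,150): the 2-of-2 region is [50,100)
  seg2 <- toy_segments(data.frame(sample_id = c("S1", "S2"), chromosome = "chr1",
                                  start_bp = c(0, 50), end_bp = c(100, 150),
                                  state = "gain"))
  cr2 <- common_regions(seg2, sub2, "gain", min_rate = 1)
  expect_equal(c(cr2$start_bp, cr2$end_bp), c(50, 100))

  # random fixture vs per-base brute force on the 10 kb toy genome
  set.seed(63)
  samples <- sprintf("S%02d", 1:6)
  sub6 <- setNames(rep(c("g1", "g2"), each = 3), samples)
  start <- sample(0:9000, 40)
  seg3 <- toy_segments(data.frame(
    sample_id = sample(samples, 40, replace = TRUE), chromosome = "chr1",
    start_bp = start, end_bp = start + sample(200:2500, 40, replace = TRUE),
    state = "gain"))
  cr3 <- common_regions(seg3, sub6, "gain", min_rate = 0.5)
  # oracle: per-base coverage counts per subgroup
  base_ok <- rep(TRUE, 12000)
  for (g in c("g1", "g2")) {
    cnt <- rep(0L, 12000)
    for (s in samples[sub6 == g]) {
      cov <- rep(FALSE, 12000)
      sc <- seg3[seg3$sample_id == s, ]
      for (i in seq_len(nrow(sc))) cov[(sc$start_bp[i] + 1):sc$end_bp[i]] <- TRUE
      cnt <- cnt + cov
    }
    base_ok <- base_ok & (cnt / 3 >= 0.5)
  }
  got <- rep(FALSE, 12000)
  for (i in seq_len(nrow(cr3))) got[(cr3$start_bp[i] + 1):cr3$end_bp[i]] <- TRUE
  expect_equal(got, base_ok)
  # reported regions never overlap and respect min_rate post hoc
  if (nrow(cr3) > 1) {
    o <- order(cr3$start_bp)
    expect_true(all(cr3$start_bp[o][-1] >= cr3$end_bp[o][-nrow(cr3)]))
  }
  expect_true(all(cr3$rate_g1 >= 0.5 & cr3$rate_g2 >= 0.5))
})

test_that("cna_expression_link enforces correlation and location rules", {
  cb <- toy_genome()
  samples <- sprintf("S%d", 1:5)
  # seg_mean on band b2 drives probe LINK located on b2; probe FAR is on b9
  segm <- c(0.1, 0.5, 0.3, 0.9, 0.7)
  seg <- toy_segments(data.frame(sample_id = samples, chromosome = "chr1",
                                 start_bp = 1000, end_bp = 2000,
                                 state = "gain", seg_mean = segm))
  v <- rbind(LINK = 7 + segm, FAR = 7 + segm, MISS = rnorm(5, 7))
  colnames(v) <- samples
  pm <- data.frame(probe_id = rownames(v), gene_symbol = rownames(v),
                   chromosome = "chr1", cytoband = c("b2", "b9", "b2"),
                   start_bp = c(1500, 8500, 1600), end_bp = c(1550, 8550, 1650))
  sm <- data.frame(sample_id = samples, is_control = FALSE,
                   subtype_label = "lumA", survival_time = NA_real_, event = NA)
  co <- expression_cohort(v, pm, sm)
  out <- cna_expression_link(seg, co, rownames(v), cb)
  expect_equal(out$probe_id, "LINK")   # FAR: high rho but wrong band
  expect_equal(out$rho, 1)

  # rho exactly 0.5 is excluded (strict threshold)
  v2 <- v
  v2["LINK", ] <- c(2, 4, 1, 3, 5)[rank(segm)]   # spearman exactly 0.5
  co2 <- expression_cohort(v2, pm, sm)
  expect_equal(cor(segm, v2["LINK", ], method = "spearman"), 0.5)
  out2 <- cna_expression_link(seg, co2, "LINK", cb)
  expect_equal(nrow(out2), 0L)
  out3 <- cna_expression_link(seg, co2, "LINK", cb, rho_min = 0.49)
  expect_equal(nrow(out3), 1L)

  expect_error(cna_expression_link(
    toy_segments(data.frame(sample_id = "OTHER", chromosome = "chr1",
                            start_bp = 0, end_bp = 10, state = "gain")),
    co, "LINK", cb), "no shared samples")
})

test_that("the generator's CNA-expression feedback is recovered end to end", {
  g <- generate_cohort(cohort_config(n_tumour = 200, n_control = 40,
                                     n_probes = 300, n_risk_probes = 20,
                                     hazard_coef = 0.7, seed = 64))
  out <- cna_expression_link(g$segments, g$cohort,
                             g$truth$planted_risk_probes, g$cytobands)
  expect_gt(nrow(out), 0)
  expect_true(all(out$probe_id %in% g$truth$planted_risk_probes))
})
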