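#' Collapse copy-number states into gain / loss / none categories
#'
#' Gains and amplifications count as `gain`; homozygous and heterozygous
#' deletions as `loss`; neutral segments as `none`.
#'
#' @param segments a `cna_segments` data.frame.
#' @return the segments with a `category` column appended.
#' @export
classify_states <- function(segments) {
  category <- c("amplification" = "gain", "gain" = "gain",
                "neutral" = "none",
                "heterozygous deletion" = "loss",
                "homozygous deletion" = "loss")[segments$state]
  segments$category <- unname(category)
  segments
}

.seg_ranges <- function(segments) {
  # internal 0-based half-open -> IRanges 1-based closed
  IRanges::IRanges(start = segments$start_bp + 1L, end = segments$end_bp)
}

.band_ranges <- function(cytobands) {
  IRanges::IRanges(start = cytobands$start_bp + 1L, end = cytobands$end_bp)
}

#' Per-cytoband gain/loss occurrence rates per subgroup
#'
#' A sample counts once per (cytoband, category) when any of its
#' segments of that category overlaps the band by at least one base.
#' Denominators are full subgroup sizes: samples without any segment
#' still count. Segments on chromosomes absent from the cytoband map are
#' skipped with a warning.
#'
#' @param segments a `cna_segments` data.frame.
#' @param cytobands a `cytoband_map`.
#' @param subgroup_assignment named vector sample id -> subgroup label,
#'   covering every sample of interest (the denominator population).
#' @return a `cytoband_profile` data.frame: chromosome, band_name,
#'   subgroup, category (gain/loss), count, n, rate.
#' @export
cytoband_occurrence <- function(segments, cytobands, subgroup_assignment) {
  seg <- classify_states(segments)
  seg <- seg[seg$category != "none" & seg$sample_id %in% names(subgroup_assignment), ]
  known <- seg$chromosome %in% cytobands$chromosome
  if (any(!known)) {
    warning("skipping ", sum(!known), " segment(s) on chromosome(s) absent ",
            "from the cytoband map: ",
            paste(unique(seg$chromosome[!known]), collapse = ", "))
    seg <- seg[known, , drop = FALSE]
  }
  sizes <- table(subgroup_assignment)
  grid <- expand.grid(band_row = seq_len(nrow(cytobands)),
                      subgroup = names(sizes),
                      category = c("gain", "loss"),
                      stringsAsFactors = FALSE)
  hits <- vector("list", nrow(seg))
  for (chr in unique(seg$chromosome)) {
    si <- which(seg$chromosome == chr)
    bi <- which(cytobands$chromosome == chr)
    ov <- IRanges::findOverlaps(.seg_ranges(seg[si, ]),
                                .band_ranges(cytobands[bi, ]))
    if (length(ov))
      hits[[si[1L]]] <- data.frame(
        band_row = bi[S4Vectors::subjectHits(ov)],
        sample_id = seg$sample_id[si[S4Vectors::queryHits(ov)]],
        category = seg$category[si[S4Vectors::queryHits(ov)]],
        stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hits)
  counts <- stats::setNames(integer(nrow(grid)), NULL)
  if (!is.null(hits) && nrow(hits)) {
    hits <- unique(hits)   # one count per sample x band x category
    hits$subgroup <- unname(subgroup_assignment[hits$sample_id])
    key_h <- paste(hits$band_row, hits$subgroup, hits$category)
    tab <- table(key_h)
    key_g <- paste(grid$band_row, grid$subgroup, grid$category)
    counts <- as.integer(tab[key_g])
    counts[is.na(counts)] <- 0L
  }
  out <- data.frame(chromosome = cytobands$chromosome[grid$band_row],
                    band_name = cytobands$band_name[grid$band_row],
                    subgroup = grid$subgroup, category = grid$category,
                    count = counts,
                    n = as.integer(sizes[grid$subgroup]),
                    stringsAsFactors = FALSE)
  out$rate <- out$count / out$n
  class(out) <- c("cytoband_profile", "data.frame")
  out
}

#' Per-band K-sample test of equal gain/loss proportions
#'
#' For each cytoband and category, tests the homogeneity of the
#' affected/unaffected split across subgroups against the pooled
#' proportion with a K x 2 chi-square test (no continuity correction).
#' Bands where the pooled count is 0 or where every sample is affected
#' carry no information and are reported with p = 1 and `degenerate =
#' TRUE`. Benjamini-Hochberg adjusted values are appended per category.
#'
#' @param profile a `cytoband_profile` from [cytoband_occurrence()].
#' @param simulate_p use simulated p-values for small counts (default
#'   FALSE).
#' @return data.frame: chromosome, band_name, category, p_value,
#'   neglog10_p, degenerate, p_adj_bh.
#' @export
proportion_test_per_band <- function(profile, simulate_p = FALSE) {
  keys <- unique(profile[, c("chromosome", "band_name", "category")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- profile[profile$chromosome == keys$chromosome[i] &
                     profile$band_name == keys$band_name[i] &
                     profile$category == keys$category[i], ]
    affected <- sub$count
    unaffected <- sub$n - sub$count
    degenerate <- sum(affected) == 0L || sum(unaffected) == 0L
    if (degenerate) {
      p <- 1
    } else {
      m <- cbind(affected, unaffected)
      p <- suppressWarnings(
        stats::chisq.test(m, correct = FALSE,
                          simulate.p.value = simulate_p)$p.value)
      if (is.na(p)) p <- 1
    }
    data.frame(chromosome = keys$chromosome[i], band_name = keys$band_name[i],
               category = keys$category[i], p_value = p,
               neglog10_p = -log10(max(p, .Machine$double.xmin)),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj_bh <- NA_real_
  for (cat in unique(out$category))
    out$p_adj_bh[out$category == cat] <-
      stats::p.adjust(out$p_value[out$category == cat], method = "BH")
  out
}

#' Genomic regions altered in at least `min_rate` of every subgroup
#'
#' Segment boundaries of the chosen category partition each chromosome
#' into atomic intervals; for every atomic interval the per-subgroup
#' fraction of covered samples is computed, and maximal runs of adjacent
#' atomic intervals where *every* subgroup's rate is at least `min_rate`
#' are returned.
#'
#' @param segments a `cna_segments` data.frame.
#' @param subgroup_assignment named vector sample id -> subgroup.
#' @param category `"gain"` or `"loss"`.
#' @param min_rate occurrence-rate threshold (default 0.5).
#' @return data.frame: chromosome, start_bp, end_bp (0-based half-open)
#'   plus one `rate_<subgroup>` column per subgroup (the minimum rate
#'   over the region's atomic intervals).
#' @export
common_regions <- function(segments, subgroup_assignment, category,
                           min_rate = 0.5) {
  stopifnot(category %in% c("gain", "loss"))
  seg <- classify_states(segments)
  seg <- seg[seg$category == category &
               seg$sample_id %in% names(subgroup_assignment), , drop = FALSE]
  groups <- sort(unique(subgroup_assignment))
  sizes <- table(subgroup_assignment)
  out <- list()
  for (chr in sort(unique(seg$chromosome))) {
    sc <- seg[seg$chromosome == chr, , drop = FALSE]
    bp <- sort(unique(c(sc$start_bp, sc$end_bp)))
    if (length(bp) < 2L) next
    atom_start <- bp[-length(bp)]
    atom_end <- bp[-1L]
    atoms <- IRanges::IRanges(start = atom_start + 1L, end = atom_end)
    # a sample covers an atom iff one of its segments contains it
    rates <- matrix(0, length(atoms), length(groups),
                    dimnames = list(NULL, groups))
    for (g in groups) {
      sg <- sc[subgroup_assignment[sc$sample_id] == g, , drop = FALSE]
      if (!nrow(sg)) next
      ov <- IRanges::findOverlaps(atoms, .seg_ranges(sg),
                                  type = "within")
      cov <- unique(data.frame(a = S4Vectors::queryHits(ov),
                               s = sg$sample_id[S4Vectors::subjectHits(ov)]))
      tab <- table(factor(cov$a, levels = seq_along(atoms)))
      rates[, g] <- as.integer(tab) / as.integer(sizes[g])
    }
    ok <- apply(rates >= min_rate, 1L, all)
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (run in which(r$values)) {
      ai <- starts[run]:ends[run]
      # merge only atoms that are truly adjacent on the genome
      brk <- c(0L, which(atom_start[ai][-1L] != atom_end[ai][-length(ai)]),
               length(ai))
      for (b in seq_len(length(brk) - 1L)) {
        piece <- ai[(brk[b] + 1L):brk[b + 1L]]
        row <- data.frame(chromosome = chr,
                          start_bp = atom_start[piece[1L]],
                          end_bp = atom_end[piece[length(piece)]],
                          stringsAsFactors = FALSE)
        for (g in groups)
          row[[paste0("rate_", g)]] <- min(rates[piece, g])
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate per-cytoband segmentation means with co-located expression
#'
#' For every (sample, cytoband) the maximal segmentation mean over the
#' sample's overlapping segments is taken (0 when the sample has no
#' segment on the band; `mode = "min"` takes the minimum instead, for
#' loss-oriented analyses). Each candidate probe is correlated
#' (Spearman) against its own cytoband's vector across the shared
#' samples; pairs with rho strictly greater than `rho_min` *and* the
#' probe annotated on that cytoband are emitted.
#'
#' @param segments a `cna_segments` data.frame.
#' @param cohort an [expression_cohort()] sharing samples with
#'   `segments`.
#' @param candidate_probes probe ids to test.
#' @param cytobands a `cytoband_map`.
#' @param rho_min correlation threshold (default 0.5, strict).
#' @param mode `"max"` (default) or `"min"` segmentation mean per band.
#' @return data.frame: chromosome, band_name, probe_id, gene_symbol,
#'   rho.
#' @export
cna_expression_link <- function(segments, cohort, candidate_probes, cytobands,
                                rho_min = 0.5, mode = c("max", "min")) {
  mode <- match.arg(mode)
  shared <- intersect(unique(segments$sample_id), colnames(cohort$values))
  if (!length(shared)) stop("no shared samples between segments and cohort")
  pm <- cohort$probe_meta[match(candidate_probes, cohort$probe_meta$probe_id), ]
  if (anyNA(pm$probe_id))
    stop("unknown probe id(s): ",
         paste(setdiff(candidate_probes, cohort$probe_meta$probe_id), collapse = ", "))
  seg <- segments[segments$sample_id %in% shared, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pm))) {
    band <- cytobands[cytobands$chromosome == pm$chromosome[i] &
                        cytobands$band_name == pm$cytoband[i], , drop = FALSE]
    if (!nrow(band)) next
    sc <- seg[seg$chromosome == band$chromosome[1L] &
                seg$start_bp < band$end_bp[1L] &
                seg$end_bp > band$start_bp[1L], , drop = FALSE]
    v <- stats::setNames(numeric(length(shared)), shared)
    if (nrow(sc)) {
      agg <- tapply(sc$seg_mean, sc$sample_id,
                    if (mode == "max") max else min)
      v[names(agg)] <- agg
    }
    expr <- cohort$values[pm$probe_id[i], shared]
    rho <- suppressWarnings(stats::cor(v, expr, method = "spearman"))
    if (!is.na(rho) && rho > rho_min)
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = pm$chromosome[i], band_name = pm$cytoband[i],
        probe_id = pm$probe_id[i], gene_symbol = pm$gene_symbol[i],
        rho = rho, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chromosome = character(0), band_name = character(0),
                      probe_id = character(0), gene_symbol = character(0),
                      rho = numeric(0)))
  do.call(rbind, rows)
}

#' Mirrored per-cytoband gain/loss bar chart as SVG
#'
#' One panel per subgroup: gains upward, losses downward, one bar per
#' cytoband in genome order; a final panel shows the -log10 p of the
#' per-band proportion test.
#'
#' @param profile a `cytoband_profile`.
#' @param tests output of [proportion_test_per_band()].
#' @param path output SVG path.
#' @return the path, invisibly.
#' @export
plot_cna_profile_svg <- function(profile, tests, path) {
  bands <- unique(profile[, c("chromosome", "band_name")])
  bands <- bands[order(bands$chromosome, bands$band_name), ]
  key <- paste(bands$chromosome, bands$band_name)
  groups <- unique(profile$subgroup)
  grDevices::svg(path, width = 10, height = 1.8 * (length(groups) + 1L))
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(length(groups) + 1L, 1L),
                       mar = c(1.5, 4, 1, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  for (g in groups) {
    sub <- profile[profile$subgroup == g, ]
    gain <- sub$rate[sub$category == "gain"][
      match(key, paste(sub$chromosome, sub$band_name)[sub$category == "gain"])]
    loss <- sub$rate[sub$category == "loss"][
      match(key, paste(sub$chromosome, sub$band_name)[sub$category == "loss"])]
    graphics::barplot(gain, ylim = c(-1, 1), col = "firebrick",
                      border = NA, main = g, ylab = "rate")
    graphics::barplot(-loss, add = TRUE, col = "steelblue", border = NA)
  }
  tg <- tests[tests$category == "gain", ]
  nl <- tg$neglog10_p[match(key, paste(tg$chromosome, tg$band_name))]
  graphics::barplot(nl, col = "grey40", border = NA,
                    main = "-log10 p (gains)", ylab = "-log10 p")
  invisible(path)
}
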