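#' Read an expression cohort from TSV files
#'
#' The matrix file has sample ids in the header and probe ids in the first
#' column; the two metadata tables are keyed by `probe_id` / `sample_id`.
#' Missing clinical fields become NA; every sample present in the matrix
#' must be described in the sample metadata.
#'
#' @param matrix_path TSV of log2 expression values.
#' @param probe_meta_path TSV with probe annotation (gene_symbol,
#'   chromosome, cytoband, start_bp, end_bp).
#' @param sample_meta_path TSV with sample annotation (is_control,
#'   subtype_label, survival_time, event, ...).
#' @return an [expression_cohort()].
#' @export
read_expression <- function(matrix_path, probe_meta_path, sample_meta_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  probe_ids <- raw[[1L]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id(s) in matrix: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(probe_ids, colnames(m))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at probe '%s', sample '%s'",
                 probe_ids[bad[1L]], colnames(m)[bad[2L]]))
  }
  pm <- utils::read.delim(probe_meta_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  sm <- utils::read.delim(sample_meta_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_samples <- setdiff(colnames(num), sm$sample_id)
  if (length(missing_samples))
    stop("sample(s) in matrix absent from metadata: ",
         paste(missing_samples, collapse = ", "))
  for (col in c("subtype_label", "survival_time", "event"))
    if (is.null(sm[[col]])) sm[[col]] <- NA
  sm <- sm[sm$sample_id %in% colnames(num), , drop = FALSE]
  pm <- pm[pm$probe_id %in% probe_ids, , drop = FALSE]
  expression_cohort(num, pm, sm)
}

#' Write an expression cohort to TSV files
#'
#' Mirrors [read_expression()]: values are serialised at full precision
#' (`format(..., digits = 17)`) so a write/read round trip is exact.
#'
#' @param cohort an [expression_cohort()].
#' @param matrix_path,probe_meta_path,sample_meta_path output paths.
#' @return the paths, invisibly.
#' @export
write_expression <- function(cohort, matrix_path, probe_meta_path, sample_meta_path) {
  vals <- format(cohort$values, digits = 17, trim = TRUE, scientific = TRUE)
  df <- data.frame(probe_id = rownames(cohort$values), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$probe_meta, probe_meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$sample_meta, sample_meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, probe_meta_path, sample_meta_path))
}

.cna_states <- c("amplification", "gain", "neutral",
                 "heterozygous deletion", "homozygous deletion")

#' Read per-sample copy-number segments
#'
#' Expects a SEG-like TSV with columns `sample_id`, `chromosome`, `start`,
#' `end`, `state`, `seg_mean`. Input coordinates are 1-based inclusive and
#' converted to the package-internal 0-based half-open convention on read.
#' State strings are case-folded against the controlled vocabulary
#' (amplification, gain, neutral, heterozygous deletion, homozygous
#' deletion).
#'
#' @param path input TSV.
#' @return a `cna_segments` data.frame with columns `sample_id`,
#'   `chromosome`, `start_bp`, `end_bp` (0-based half-open), `state`,
#'   `seg_mean`.
#' @export
read_cna_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chromosome", "start", "end", "state", "seg_mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  state <- tolower(trimws(df$state))
  bad <- setdiff(unique(state), .cna_states)
  if (length(bad)) stop("unknown CNA state(s): ", paste(bad, collapse = ", "))
  if (any(df$end < df$start))
    stop("segment end < start for sample(s): ",
         paste(unique(df$sample_id[df$end < df$start]), collapse = ", "))
  cna_segments(data.frame(
    sample_id = df$sample_id, chromosome = df$chromosome,
    start_bp = df$start - 1L, end_bp = df$end,
    state = state, seg_mean = df$seg_mean, stringsAsFactors = FALSE))
}

#' Construct a validated segment set (internal coordinates)
#' @param df data.frame with `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp` (0-based half-open), `state`, `seg_mean`.
#' @return the data.frame with class `cna_segments` prepended.
#' @export
cna_segments <- function(df) {
  stopifnot(all(c("sample_id", "chromosome", "start_bp", "end_bp",
                  "state", "seg_mean") %in% names(df)))
  bad <- setdiff(unique(df$state), .cna_states)
  if (length(bad)) stop("unknown CNA state(s): ", paste(bad, collapse = ", "))
  if (any(df$end_bp <= df$start_bp)) stop("segments must satisfy end_bp > start_bp")
  class(df) <- c("cna_segments", "data.frame")
  df
}

#' Write copy-number segments (1-based inclusive on disk)
#' @param segments a `cna_segments` data.frame.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_cna_segments <- function(segments, path) {
  out <- data.frame(sample_id = segments$sample_id,
                    chromosome = segments$chromosome,
                    start = segments$start_bp + 1L,
                    end = segments$end_bp,
                    state = segments$state,
                    seg_mean = format(segments$seg_mean, digits = 17, trim = TRUE),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a UCSC-style cytoband table
#'
#' Layout of `cytoBand.txt`: chrom, chromStart, chromEnd, name, gieStain,
#' no header, already 0-based half-open. Bands must be non-overlapping
#' within a chromosome; they are returned sorted.
#'
#' @param path input file.
#' @return a `cytoband_map` data.frame with columns `chromosome`,
#'   `start_bp`, `end_bp`, `band_name`.
#' @export
read_cytobands <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chromosome", "start_bp", "end_bp", "band_name")
  cytoband_map(df[, 1:4])
}

#' Construct a validated cytoband map
#' @param df data.frame with `chromosome`, `start_bp`, `end_bp`,
#'   `band_name` (0-based half-open).
#' @return the sorted data.frame with class `cytoband_map`.
#' @export
cytoband_map <- function(df) {
  stopifnot(all(c("chromosome", "start_bp", "end_bp", "band_name") %in% names(df)))
  if (any(df$end_bp <= df$start_bp)) stop("cytobands must satisfy end_bp > start_bp")
  df <- df[order(df$chromosome, df$start_bp), , drop = FALSE]
  rownames(df) <- NULL
  for (chr in unique(df$chromosome)) {
    sub <- df[df$chromosome == chr, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start_bp[-1L] < sub$end_bp[-nrow(sub)]))
      stop("overlapping cytobands on ", chr)
  }
  class(df) <- c("cytoband_map", "data.frame")
  df
}

#' Write a cytoband map in UCSC layout
#' @param cytobands a `cytoband_map`.
#' @param path output file (no header, gieStain filled with `gneg`).
#' @return the path, invisibly.
#' @export
write_cytobands <- function(cytobands, path) {
  out <- data.frame(cytobands$chromosome, cytobands$start_bp,
                    cytobands$end_bp, cytobands$band_name, "gneg")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Locate genomic positions in a cytoband map
#' @param cytobands a `cytoband_map`.
#' @param chromosome,position vectors of query positions (0-based).
#' @return character vector of band names (NA when not covered).
#' @export
lookup_cytoband <- function(cytobands, chromosome, position) {
  mapply(function(chr, pos) {
    hit <- cytobands$chromosome == chr &
      cytobands$start_bp <= pos & pos < cytobands$end_bp
    if (any(hit)) cytobands$band_name[which(hit)[1L]] else NA_character_
  }, chromosome, position, USE.NAMES = FALSE)
}

#' Map probes between platforms by shared gene symbol
#'
#' Each source probe whose gene symbol occurs in the target cohort is
#' paired with exactly one target probe. When several target probes carry
#' the symbol, the one with the largest expression range (max - min across
#' target samples) is chosen; range ties break to the lexicographically
#' smaller target probe id. Source probes with an empty symbol are skipped
#' with a warning.
#'
#' @param source,target [expression_cohort()] objects with `gene_symbol`
#'   annotation.
#' @return a `probe_mapping` data.frame with `source_probe_id`,
#'   `target_probe_id`, `gene_symbol`; unmapped source probes are listed
#'   in `attr(, "unmapped")`.
#' @export
map_probes_by_symbol <- function(source, target) {
  src_sym <- source$probe_meta$gene_symbol
  empty <- is.na(src_sym) | src_sym == ""
  if (any(empty))
    warning(sum(empty), " source probe(s) without gene symbol skipped")
  tgt_rng <- apply(target$values, 1L, function(v) max(v) - min(v))
  tgt <- data.frame(probe_id = target$probe_meta$probe_id,
                    gene_symbol = target$probe_meta$gene_symbol,
                    rng = tgt_rng[target$probe_meta$probe_id],
                    stringsAsFactors = FALSE)
  # per symbol: largest range, ties to the lexicographically smaller id
  tgt <- tgt[order(tgt$gene_symbol, -tgt$rng, tgt$probe_id, method = "radix"), ]
  best <- tgt[!duplicated(tgt$gene_symbol), ]
  idx <- match(src_sym, best$gene_symbol)
  ok <- !empty & !is.na(idx)
  out <- data.frame(
    source_probe_id = source$probe_meta$probe_id[ok],
    target_probe_id = best$probe_id[idx[ok]],
    gene_symbol = src_sym[ok],
    stringsAsFactors = FALSE)
  out <- out[order(out$source_probe_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- source$probe_meta$probe_id[!ok & !empty]
  attr(out, "resolution_rule") <- "max_range_lexicographic"
  class(out) <- c("probe_mapping", "data.frame")
  out
}
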