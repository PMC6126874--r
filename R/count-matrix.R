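# Window x sample accessibility matrices: read counting over the tiling and
# the depth-normalized log transform.

#' Construct a window x sample count matrix
#'
#' @param windows Window data.frame from [tile_genome()] (columns chrom,
#'   start, end, id).
#' @param samples A sample_sheet.
#' @param values Numeric matrix, windows x samples.
#' @param stage "raw" (non-negative integer counts) or "log"
#'   (depth-normalized ln(x+1) values).
#' @return A `count_matrix`.
#' @export
count_matrix <- function(windows, samples, values, stage = "raw") {
  new_count_matrix(windows, samples, values, stage)
}

new_count_matrix <- function(windows, samples, values, stage) {
  stopifnot(stage %in% c("raw", "log"))
  values <- as.matrix(values)
  if (nrow(values) != nrow(windows) || ncol(values) != nrow(samples))
    stop_("count matrix: dimensions inconsistent with windows/samples")
  rownames(values) <- windows$id
  colnames(values) <- samples$sample_id
  if (stage == "raw" && any(values < 0 | values != floor(values)))
    stop_("count matrix: raw stage requires non-negative integer counts")
  if (stage == "log" && any(values < 0))
    stop_("count matrix: log stage values must be >= 0")
  structure(list(windows = windows, samples = samples, values = values,
                 stage = stage),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix [%s]: %d windows x %d samples, %d cell types>\n",
              x$stage, nrow(x$values), ncol(x$values),
              n_cell_types(x$samples)))
  invisible(x)
}

#' Count read 5' ends per window per sample
#'
#' Each aligned read is assigned to at most one window by its strand-aware
#' 5' end (start for plus-strand reads, end - 1 for minus-strand reads),
#' so reads are never double-counted across the non-overlapping tiling.
#'
#' @param windows Window data.frame from [tile_genome()].
#' @param reads Named list (one entry per sample, names = sample ids) of
#'   interval data.frames with columns `chrom`, `start`, `end` and
#'   optionally `strand` ("+" assumed when absent).
#' @param samples A sample_sheet covering exactly the names of `reads`.
#' @return A raw-stage `count_matrix`.
#' @export
count_reads <- function(windows, reads, samples) {
  if (!all(samples$sample_id %in% names(reads)))
    stop_("count_reads: reads missing for sample(s): %s",
          paste(setdiff(samples$sample_id, names(reads)), collapse = ", "))
  known <- unique(windows$chrom)
  vals <- vapply(samples$sample_id, function(sid) {
    r <- reads[[sid]]
    cnt <- integer(nrow(windows))
    if (NROW(r) == 0L) return(cnt)
    validate_intervals(r, sprintf("reads[%s]", sid))
    strand <- if ("strand" %in% names(r)) as.character(r$strand) else
      rep("+", nrow(r))
    pos <- ifelse(strand == "-", r$end - 1L, r$start)
    bad <- !(r$chrom %in% known)
    if (any(bad)) {
      warning(sprintf("count_reads: %d read(s) of %s on unknown chromosome, skipped",
                      sum(bad), sid), call. = FALSE)
      r <- r[!bad, , drop = FALSE]
      pos <- pos[!bad]
    }
    for (ch in unique(r$chrom)) {
      wi <- which(windows$chrom == ch)
      p <- pos[r$chrom == ch]
      wr <- IRanges::IRanges(start = windows$start[wi] + 1L,
                             end = windows$end[wi])
      pr <- IRanges::IRanges(start = p + 1L, width = 1L)
      cnt[wi] <- cnt[wi] + IRanges::countOverlaps(wr, pr)
    }
    cnt
  }, integer(nrow(windows)))
  new_count_matrix(windows, samples, vals, "raw")
}

#' Depth-normalize raw counts and log-transform
#'
#' Scales each sample's counts by factor_i = (grand mean read count) /
#' (sample i's mean read count), then applies ln(x + 1). Scaling before the
#' log keeps the pseudocount independent of sequencing depth.
#'
#' @param raw A raw-stage count_matrix.
#' @param grand_mean Either "entries" (grand mean over all matrix entries,
#'   default) or "sample_means" (mean of the per-sample means); the two
#'   coincide when all samples cover the same windows, which they do here,
#'   so the switch only matters for unbalanced extensions.
#' @return A log-stage count_matrix.
#' @export
normalize_log <- function(raw, grand_mean = c("entries", "sample_means")) {
  grand_mean <- match.arg(grand_mean)
  if (raw$stage != "raw") stop_("normalize_log: expected a raw-stage matrix")
  smeans <- colMeans(raw$values)
  if (any(smeans == 0))
    stop_("normalize_log: sample(s) with all-zero counts: %s",
          paste(names(smeans)[smeans == 0], collapse = ", "))
  g <- if (grand_mean == "entries") mean(raw$values) else mean(smeans)
  factors <- g / smeans
  vals <- log(sweep(raw$values, 2L, factors, `*`) + 1)
  out <- new_count_matrix(raw$windows, raw$samples, vals, "log")
  attr(out, "depth_factors") <- factors
  out
}

#' Read a window x sample count matrix from TSV
#' @param path TSV with a `window_id` first column and one column per sample.
#' @param samples sample_sheet naming the sample columns.
#' @param windows Optional window data.frame; when missing, coordinates are
#'   recovered from the "chrom:start-end" ids.
#' @param stage "raw" or "log".
#' @export
read_count_matrix <- function(path, samples, windows = NULL, stage = "raw") {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "window_id")
    stop_("read_count_matrix: first column must be window_id")
  ids <- tab$window_id
  if (is.null(windows)) windows <- windows_from_ids(ids)
  miss <- setdiff(samples$sample_id, names(tab))
  if (length(miss))
    stop_("read_count_matrix: missing sample column(s): %s",
          paste(miss, collapse = ", "))
  vals <- as.matrix(tab[, samples$sample_id, drop = FALSE])
  new_count_matrix(windows, samples, vals, stage)
}

#' Write a count matrix as TSV
#' @param mat A count_matrix.
#' @param path Output path.
#' @export
write_count_matrix <- function(mat, path) {
  out <- data.frame(window_id = mat$windows$id, mat$values,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Recover window coordinates from "chrom:start-end" ids.
windows_from_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  if (any(lengths(m) != 4L))
    stop_("cannot parse window id(s): %s",
          paste(head(ids[lengths(m) != 4L], 3), collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             id = ids, stringsAsFactors = FALSE)
}
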