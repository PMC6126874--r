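# Genome tiling into fixed-width windows and BED interval IO.
# All coordinates are 0-based half-open (BED convention); a window id is
# "chrom:start-end" and is the stable key used across the whole pipeline.

window_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Tile a genome into fixed-width non-overlapping windows
#'
#' Cuts every chromosome into consecutive windows of `width` base pairs,
#' dropping the trailing sub-width remainder, and removes any window that
#' overlaps a blacklist interval (typically strong repeats) by at least
#' `min_overlap` base pairs.
#'
#' @param genome_lengths Named numeric vector of chromosome lengths in bp.
#' @param width Window width in bp (default 200).
#' @param blacklist Optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of regions to exclude.
#' @param min_overlap Minimum overlap in bp for a window to be removed
#'   (default 1, i.e. any overlap).
#' @return A data.frame with columns `chrom`, `start`, `end`, `id`, sorted by
#'   (chrom, start); windows are pairwise disjoint.
#' @examples
#' tile_genome(c(chr1 = 450), width = 200)
#' @export
tile_genome <- function(genome_lengths, width = 200L, blacklist = NULL,
                        min_overlap = 1L) {
  if (length(genome_lengths) == 0L)
    stop_("tile_genome: empty genome_lengths")
  if (is.null(names(genome_lengths)) || any(!nzchar(names(genome_lengths))))
    stop_("tile_genome: genome_lengths must be named by chromosome")
  if (!is_count(width) || width < 1)
    stop_("tile_genome: width must be a positive integer")
  if (any(genome_lengths < 0))
    stop_("tile_genome: negative chromosome length")

  chroms <- sort(names(genome_lengths), method = "radix")
  parts <- lapply(chroms, function(ch) {
    n <- floor(genome_lengths[[ch]] / width)
    if (n < 1) return(NULL)
    start <- as.integer(seq.int(0L, by = width, length.out = n))
    data.frame(chrom = ch, start = start, end = start + as.integer(width),
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, parts)
  if (is.null(win))
    win <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)

  if (!is.null(blacklist) && nrow(win) > 0 && NROW(blacklist) > 0) {
    validate_intervals(blacklist, "blacklist")
    keep <- !overlaps_any(win, blacklist, min_overlap = min_overlap)
    win <- win[keep, , drop = FALSE]
  }
  win$id <- window_id(win$chrom, win$start, win$end)
  rownames(win) <- NULL
  win
}

validate_intervals <- function(x, what) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop_("%s: expected columns chrom, start, end", what)
  if (any(x$start < 0) || any(x$end < x$start))
    stop_("%s: negative or inverted interval", what)
  invisible(x)
}

# TRUE for each query interval overlapping any subject interval by
# >= min_overlap bp. Half-open coordinates; uses IRanges per chromosome.
overlaps_any <- function(query, subject, min_overlap = 1L) {
  hit <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0L) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L,
                           end = subject$end[si])
    ov <- IRanges::findOverlaps(qr, sr, minoverlap = min_overlap)
    hit[qi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}

#' Read a BED3+ file into a 0-based half-open interval data.frame
#' @param path Path to a BED file (no header).
#' @return data.frame with columns chrom, start, end (and name if present).
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop_("read_bed: %s has fewer than 3 columns", path)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  validate_intervals(x, path)
  x
}

#' Write intervals as BED
#' @param x data.frame with chrom, start, end and optionally a name column.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "write_bed")
  cols <- c("chrom", "start", "end", intersect("name", names(x)))
  if (!"name" %in% names(x) && "id" %in% names(x)) {
    x$name <- x$id
    cols <- c("chrom", "start", "end", "name")
  }
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
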