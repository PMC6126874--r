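# TRANSFAC flat-file motif matrices: parsing, writing and small helpers.
# A motif is a list(motif_id, name, counts) where counts is a width x 4
# matrix with columns A, C, G, T of non-negative base counts.

DNA_BASES <- c("A", "C", "G", "T")

new_motif_matrix <- function(motif_id, name, counts) {
  counts <- as.matrix(counts)
  colnames(counts) <- DNA_BASES
  if (nrow(counts) < 1) stop_("motif %s: width must be >= 1", motif_id)
  if (any(counts < 0)) stop_("motif %s: negative count", motif_id)
  if (any(rowSums(counts) == 0))
    stop_("motif %s: position with all-zero counts", motif_id)
  structure(list(motif_id = motif_id, name = name, counts = counts,
                 width = nrow(counts)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif %s (%s), width %d, consensus %s>\n",
              x$motif_id, x$name, x$width, motif_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a motif (most frequent base per position)
#' @param motif A motif_matrix.
#' @return Character scalar over A/C/G/T; ties go to the first base in
#'   alphabetical order.
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$counts, 1L, which.max)], collapse = "")
}

#' Parse motifs from a TRANSFAC flat file
#'
#' Understands the count-matrix dialect: records delimited by `//`, with
#' `AC` (accession), `ID`/`NA` (name), a `P0` (or `PO`) header naming the
#' base column order, and numbered rows `01  countA countC countG countT`
#' optionally followed by a consensus letter.
#'
#' @param x Path to a file, or a character vector of lines.
#' @return A named list of `motif_matrix` objects (names = motif ids).
#' @export
parse_transfac <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else
    unlist(strsplit(x, "\n", fixed = TRUE))
  recs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || length(cur$rows) == 0L) return(NULL)
    counts <- do.call(rbind, cur$rows)
    colnames(counts) <- cur$order
    counts <- counts[, DNA_BASES, drop = FALSE]
    id <- cur$ac %||% cur$id %||% sprintf("motif_%d", length(recs) + 1L)
    new_motif_matrix(id, cur$name %||% cur$id %||% id, counts)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "XX") || startsWith(ln, "CC")) next
    if (startsWith(ln, "//")) {
      m <- flush(cur)
      if (!is.null(m)) recs[[m$motif_id]] <- m
      cur <- NULL
      next
    }
    if (is.null(cur)) cur <- list(rows = list(), order = DNA_BASES)
    tag <- substr(ln, 1, 2)
    rest <- trimws(substr(ln, 3, nchar(ln)))
    if (tag == "AC") { cur$ac <- rest; next }
    if (tag == "ID") { cur$id <- rest; next }
    if (tag == "NA") { cur$name <- rest; next }
    if (tag %in% c("P0", "PO")) {
      ord <- strsplit(rest, "\\s+")[[1]]
      if (!setequal(ord, DNA_BASES))
        stop_("parse_transfac: line %d: bad base header '%s'", i, ln)
      cur$order <- ord
      next
    }
    if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(f[2:min(5, length(f))]))
      if (length(vals) != 4L || anyNA(vals))
        stop_("parse_transfac: line %d: expected 4 numeric counts in '%s'",
              i, ln)
      if (any(vals < 0))
        stop_("parse_transfac: line %d: negative count in '%s'", i, ln)
      cur$rows[[length(cur$rows) + 1L]] <- vals
      next
    }
    # unrecognised tags (DE, BF, ...) are metadata; skip
  }
  m <- flush(cur)
  if (!is.null(m)) recs[[m$motif_id]] <- m
  recs
}

#' Write motifs to TRANSFAC flat-file text
#' @param motifs List of motif_matrix objects.
#' @param path Optional output path; if missing, the text is returned.
#' @return The lines, invisibly if written to a file.
#' @export
write_transfac <- function(motifs, path = NULL) {
  out <- unlist(lapply(motifs, function(m) {
    rows <- vapply(seq_len(m$width), function(j) {
      sprintf("%02d  %s", j, paste(format(m$counts[j, ], trim = TRUE),
                                   collapse = "  "))
    }, character(1))
    c(sprintf("AC  %s", m$motif_id),
      "XX",
      sprintf("ID  %s", m$name),
      "XX",
      "P0      A  C  G  T",
      rows,
      "XX",
      "//")
  }))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
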