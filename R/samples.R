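# Sample sheets (sample -> cell type) and motif -> TF-group maps.

#' Load a sample sheet mapping samples to cell types
#'
#' Each DNase-seq sample (replicates count as separate samples) belongs to
#' exactly one cell type; a cell type may pool several biologically similar
#' cell lines.
#'
#' @param x Path to a TSV with header columns `sample_id` and `cell_type`
#'   (optionally `file_path`), or an equivalent data.frame.
#' @return A `sample_sheet` data.frame; `n_samples()` and `n_cell_types()`
#'   report n and m.
#' @export
load_sample_map <- function(x) {
  tab <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else
    as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cell_type") %in% names(tab)))
    stop_("sample sheet: columns sample_id and cell_type are required")
  if (nrow(tab) == 0L) stop_("sample sheet: no samples")
  tab$sample_id <- as.character(tab$sample_id)
  tab$cell_type <- as.character(tab$cell_type)
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup))
    stop_("sample sheet: duplicate sample_id: %s",
          paste(unique(dup), collapse = ", "))
  if (any(is.na(tab$cell_type) | !nzchar(tab$cell_type)))
    stop_("sample sheet: sample with empty cell_type")
  class(tab) <- c("sample_sheet", "data.frame")
  tab
}

#' @rdname load_sample_map
#' @param sheet A sample_sheet.
#' @export
n_samples <- function(sheet) nrow(sheet)

#' @rdname load_sample_map
#' @export
n_cell_types <- function(sheet) length(unique(sheet$cell_type))

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("<sample_sheet: n = %d samples, m = %d cell types>\n",
              n_samples(x), n_cell_types(x)))
  NextMethod()
}

#' Load a motif -> TF-group map
#'
#' Distinct motifs can represent one factor and similar motifs several
#' factors, so motifs are collapsed to curated TF groups/families before
#' pair testing; the map is treated as opaque curated input.
#'
#' @param x Path to a TSV with header columns `motif_id` and `tf_group`, or
#'   an equivalent data.frame.
#' @return A named character vector (names = motif ids, values = group ids)
#'   of class `motif_group_map`.
#' @export
load_motif_group_map <- function(x) {
  tab <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else
    as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("motif_id", "tf_group") %in% names(tab)))
    stop_("motif group map: columns motif_id and tf_group are required")
  if (nrow(tab) == 0L) stop_("motif group map: empty map")
  tab$motif_id <- as.character(tab$motif_id)
  tab$tf_group <- as.character(tab$tf_group)
  if (any(is.na(tab$tf_group) | !nzchar(tab$tf_group)))
    stop_("motif group map: motif with empty tf_group")
  grp <- split(tab$tf_group, tab$motif_id)
  bad <- names(grp)[vapply(grp, function(g) length(unique(g)) > 1L,
                           logical(1))]
  if (length(bad))
    stop_("motif group map: motif(s) mapped to multiple groups: %s",
          paste(bad, collapse = ", "))
  tab <- tab[!duplicated(tab$motif_id), , drop = FALSE]
  structure(setNames(tab$tf_group, tab$motif_id),
            class = "motif_group_map")
}

#' @export
print.motif_group_map <- function(x, ...) {
  cat(sprintf("<motif_group_map: %d motifs in %d TF groups>\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Number of unordered cross-group motif pairs under a group map
#'
#' Counts motif pairs whose two motifs belong to different TF groups; these
#' are the pairs actually tested (same-group pairs are excluded because the
#' method is insensitive to homotypic co-occurrence).
#'
#' @param groups A motif_group_map (or named character vector).
#' @return Integer pair count, equal to C(n,2) minus the within-group pairs.
#' @export
count_cross_group_pairs <- function(groups) {
  n <- length(groups)
  sizes <- table(unclass(groups))
  as.integer(choose(n, 2) - sum(choose(sizes, 2)))
}
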