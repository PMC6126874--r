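# The regularized t-statistic that ranks windows by cell-type specificity,
# and the selection of the top-l cell-type-specific (CTS) and top-l
# ubiquitously open (ubiq) DHSs.

#' Cell-type specificity t-statistic per window per cell type
#'
#' For every window, cell-type means of the log-normalized counts are
#' contrasted with the global profile (the unweighted mean of the cell-type
#' means) and scaled by a regularized pooled within-cell-type standard
#' deviation:
#'
#'   t_ct = (Xbar_ct - Xbar) / ( sqrt(1/m + 1/n_ct) * (s + s0) )
#'
#' where s is the pooled within-class SD of the window and s0, the mean of s
#' over all windows, guards against division by small variance estimates.
#' Cell types with a single sample contribute nothing to s (their n_ct - 1
#' degrees of freedom are zero) but still receive a t value.
#'
#' @param logmat A log-stage count_matrix with at least two cell types.
#' @param s0 Optional regularizer override; defaults to mean(s) over windows.
#' @param denominator Radical placement in the denominator:
#'   `"sum"` (default) uses sqrt(1/m + 1/n_ct) * (s + s0);
#'   `"sqrt-inside"` uses sqrt((1/m + 1/n_ct) * (s + s0)).
#' @return A `specificity_result` with fields `t` (window x cell type
#'   matrix), `s`, `s0`, `cell_means`, `global_mean` and `windows`.
#' @export
t_statistic <- function(logmat, s0 = NULL,
                        denominator = c("sum", "sqrt-inside")) {
  denominator <- match.arg(denominator)
  if (logmat$stage != "log")
    stop_("t_statistic: expected a log-stage matrix (see normalize_log)")
  samples <- logmat$samples
  cts <- sort(unique(samples$cell_type), method = "radix")
  m <- length(cts)
  if (m < 2) stop_("t_statistic: need at least 2 cell types, got %d", m)
  X <- logmat$values
  idx <- lapply(cts, function(ct) which(samples$cell_type == ct))
  n_ct <- lengths(idx)

  cell_means <- vapply(idx, function(i) rowMeans(X[, i, drop = FALSE]),
                       numeric(nrow(X)))
  colnames(cell_means) <- cts
  global_mean <- rowMeans(cell_means)

  df <- sum(n_ct - 1L)
  if (df == 0L)
    stop_("t_statistic: all cell types have a single sample; pooled SD undefined")
  ss <- numeric(nrow(X))
  for (j in seq_along(cts)) {
    if (n_ct[j] < 2L) next
    dev <- X[, idx[[j]], drop = FALSE] - cell_means[, j]
    ss <- ss + rowSums(dev^2)
  }
  s <- sqrt(ss / df)
  if (is.null(s0)) s0 <- mean(s)

  w_ct <- 1 / m + 1 / n_ct
  num <- cell_means - global_mean
  tmat <- if (denominator == "sum") {
    num / (outer(s + s0, sqrt(w_ct)))
  } else {
    num / sqrt(outer(s + s0, w_ct))
  }
  # a window with zero deviation and zero pooled variance everywhere
  # (e.g. a constant matrix) is not specific: 0/0 -> 0
  tmat[num == 0] <- 0
  colnames(tmat) <- cts
  rownames(tmat) <- logmat$windows$id
  structure(list(t = tmat, s = s, s0 = s0, cell_means = cell_means,
                 global_mean = global_mean, windows = logmat$windows,
                 n_ct = setNames(n_ct, cts), m = m),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("<specificity_result: %d windows x %d cell types, s0 = %.4g>\n",
              nrow(x$t), ncol(x$t), x$s0))
  invisible(x)
}

#' Select the top-l cell-type-specific windows per cell type
#'
#' @param spec A specificity_result.
#' @param l Number of windows per cell type.
#' @return A named list (cell type -> character vector of l window ids,
#'   descending t; ties broken by genomic coordinate).
#' @export
select_cts <- function(spec, l) {
  nw <- nrow(spec$t)
  if (!is_count(l) || l < 1) stop_("select_cts: l must be a positive integer")
  if (l > nw) stop_("select_cts: l = %d exceeds %d windows", l, nw)
  w <- spec$windows
  out <- lapply(colnames(spec$t), function(ct) {
    o <- order(-spec$t[, ct], w$chrom, w$start, method = "radix")
    w$id[o[seq_len(l)]]
  })
  setNames(out, colnames(spec$t))
}

#' Select the top-l ubiquitously open windows
#'
#' Eligible windows are those whose global mean accessibility strictly
#' exceeds the `open_quantile` quantile of all global means (openness
#' filter); among them, the l windows with smallest max_ct |t_ct| are taken,
#' ascending, ties broken by genomic coordinate.
#'
#' @param spec A specificity_result.
#' @param l Number of windows.
#' @param open_quantile Openness quantile threshold (default 0.75).
#' @return Character vector of l window ids.
#' @export
select_ubiq <- function(spec, l, open_quantile = 0.75) {
  if (!is_count(l) || l < 1) stop_("select_ubiq: l must be a positive integer")
  thr <- quantile(spec$global_mean, open_quantile, names = FALSE)
  eligible <- which(spec$global_mean > thr)
  if (length(eligible) < l)
    stop_("select_ubiq: only %d eligible windows (need l = %d)",
          length(eligible), l)
  w <- spec$windows
  score <- apply(abs(spec$t[eligible, , drop = FALSE]), 1L, max)
  o <- order(score, w$chrom[eligible], w$start[eligible], method = "radix")
  w$id[eligible[o[seq_len(l)]]]
}

#' Bundle CTS and ubiquitous selections
#'
#' @param spec A specificity_result.
#' @param l Windows per stratum (the atlas-scale default is 5000; synthetic
#'   fixtures use smaller l).
#' @param open_quantile Passed to [select_ubiq()].
#' @return A `dhs_selection`: list(cts = per-cell-type id lists, ubiq = ids,
#'   l, windows).
#' @export
select_dhs <- function(spec, l, open_quantile = 0.75) {
  sel <- list(cts = select_cts(spec, l),
              ubiq = select_ubiq(spec, l, open_quantile),
              l = as.integer(l),
              windows = spec$windows)
  # a window can be CTS for one cell type and ubiquitous in principle;
  # within one cell type the two strata must be disjoint to stratify by Z
  for (ct in names(sel$cts)) {
    clash <- intersect(sel$cts[[ct]], sel$ubiq)
    if (length(clash))
      stop_("select_dhs: %d window(s) selected as both CTS (%s) and ubiquitous; increase data size or lower l",
            length(clash), ct)
  }
  class(sel) <- "dhs_selection"
  sel
}

#' @export
print.dhs_selection <- function(x, ...) {
  cat(sprintf("<dhs_selection: l = %d, %d cell types>\n",
              x$l, length(x$cts)))
  invisible(x)
}

#' Summarize GC content and annotation overlap of selected DHSs
#'
#' @param selection A dhs_selection.
#' @param genome A named [Biostrings::DNAStringSet] (names = chromosomes).
#' @param annotations Optional named list of interval data.frames (chrom,
#'   start, end); overlap of >= 1 bp counts.
#' @return data.frame with one row per DHS set (each cell type's CTS set and
#'   the ubiq set): mean GC fraction and the fraction of windows overlapping
#'   each annotation set.
#' @export
characterize_dhs <- function(selection, genome, annotations = list()) {
  sets <- c(setNames(selection$cts,
                     paste0("cts:", names(selection$cts))),
            list(ubiq = selection$ubiq))
  w <- selection$windows
  rows <- lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    sub <- w[match(ids, w$id), , drop = FALSE]
    seqs <- window_sequences(sub, genome)
    freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    gc <- rowSums(freq[, c("C", "G"), drop = FALSE]) / rowSums(freq)
    row <- data.frame(set = nm, n = length(ids), mean_gc = mean(gc),
                      stringsAsFactors = FALSE)
    for (an in names(annotations)) {
      hit <- overlaps_any(sub, annotations[[an]], min_overlap = 1L)
      row[[paste0("frac_", an)]] <- mean(hit)
    }
    row
  })
  do.call(rbind, rows)
}

# Extract window sequences from a named DNAStringSet genome.
window_sequences <- function(windows, genome) {
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  miss <- setdiff(unique(windows$chrom), names(genome))
  if (length(miss))
    stop_("genome is missing chromosome(s): %s", paste(miss, collapse = ", "))
  too_far <- windows$end > Biostrings::width(genome)[match(windows$chrom,
                                                           names(genome))]
  if (any(too_far))
    stop_("window(s) beyond chromosome end: %s",
          paste(head(windows$id[too_far], 3), collapse = ", "))
  out <- Biostrings::subseq(genome[windows$chrom],
                            start = windows$start + 1L,
                            end = windows$end)
  names(out) <- windows$id
  out
}
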