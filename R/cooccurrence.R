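# The statistical core: stratified 2x2 co-binding tables per motif pair,
# one-sided Fisher log p-values on the CTS and ubiquitous strata, the L
# score, empirical-quantile significance, BH correction, aggregation of
# motif pairs to TF-group pairs, and single-motif overrepresentation.

#' Build the two stratified 2x2 co-binding tables for one motif pair
#'
#' Over the joint 2l DHS stratum of one cell type, counts DHSs by bound
#' status of motif a (rows), bound status of motif b (columns), separately
#' on the cell-type-specific stratum (z = TRUE) and the ubiquitous stratum
#' (z = FALSE). Each table sums to l.
#'
#' @param calls_a,calls_b Logical bound vectors of length 2l.
#' @param z Logical CTS indicator of length 2l with exactly l TRUE entries.
#' @return A `pair_tables` list with 2x2 matrices `cts` and `ubiq`
#'   (rows = a bound/unbound, columns = b bound/unbound).
#' @export
build_pair_tables <- function(calls_a, calls_b, z) {
  n <- length(z)
  if (length(calls_a) != n || length(calls_b) != n)
    stop_("build_pair_tables: vector lengths differ (%d, %d, %d)",
          length(calls_a), length(calls_b), n)
  if (!is.logical(calls_a) || !is.logical(calls_b) || !is.logical(z))
    stop_("build_pair_tables: inputs must be logical vectors")
  if (2L * sum(z) != n)
    stop_("build_pair_tables: z must mark exactly half of the 2l DHSs as CTS")
  tab <- function(sel) {
    a <- calls_a[sel]; b <- calls_b[sel]
    matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
           nrow = 2L, byrow = TRUE,
           dimnames = list(a = c("bound", "unbound"),
                           b = c("bound", "unbound")))
  }
  structure(list(cts = tab(z), ubiq = tab(!z)), class = "pair_tables")
}

#' Score all cross-group motif pairs of one cell type
#'
#' Enumerates every unordered motif pair whose two motifs belong to
#' different TF groups (same-group pairs are skipped: the method is
#' insensitive to homotypic pairs), builds the stratified tables, and
#' computes the upper-tail log Fisher p-values and the L score. The n11
#' counts for all pairs are obtained with one cross-product per stratum.
#'
#' @param calls A binding_calls object.
#' @param groups A motif_group_map covering every scored motif.
#' @param cell_type Cell type to score (must be present in `calls`).
#' @return data.frame with one row per cross-group pair: cell_type, motif_a,
#'   motif_b, tf_a, tf_b, n11_cts, n11_ubiq, log_p_cts, log_p_ubiq, L.
#' @export
score_all_pairs <- function(calls, groups, cell_type) {
  if (!cell_type %in% names(calls$calls))
    stop_("score_all_pairs: unknown cell type '%s'", cell_type)
  B <- calls$calls[[cell_type]]
  motifs <- colnames(B)
  miss <- setdiff(motifs, names(groups))
  if (length(miss))
    stop_("score_all_pairs: motif(s) missing from group map: %s",
          paste(head(miss, 3), collapse = ", "))
  g <- unclass(groups)[motifs]
  z <- calls$z[[cell_type]]
  l <- sum(z)

  idx <- which(outer(g, g, `!=`) & upper.tri(matrix(0, length(g), length(g))),
               arr.ind = TRUE)
  if (nrow(idx) == 0L)  # all motifs in one TF group: nothing to test
    return(data.frame(cell_type = character(), motif_a = character(),
                      motif_b = character(), tf_a = character(),
                      tf_b = character(), n11_cts = integer(),
                      n11_ubiq = integer(), log_p_cts = numeric(),
                      log_p_ubiq = numeric(), L = numeric(),
                      stringsAsFactors = FALSE))
  ia <- idx[, 1L]; ib <- idx[, 2L]

  Bc <- B[z, , drop = FALSE] * 1L
  Bu <- B[!z, , drop = FALSE] * 1L
  n11c_all <- crossprod(Bc)
  n11u_all <- crossprod(Bu)
  kc <- colSums(Bc)   # bound-in-CTS margin per motif
  ku <- colSums(Bu)

  n11c <- n11c_all[cbind(ia, ib)]
  n11u <- n11u_all[cbind(ia, ib)]
  lp <- function(n11, ka, kb) {
    # margins: a bound = ka, b bound = kb, total l
    phyper(n11 - 1, m = ka, n = l - ka, k = kb,
           lower.tail = FALSE, log.p = TRUE)
  }
  log_p_cts <- pmin(lp(n11c, kc[ia], kc[ib]), 0)
  log_p_ubiq <- pmin(lp(n11u, ku[ia], ku[ib]), 0)

  data.frame(cell_type = cell_type,
             motif_a = motifs[ia], motif_b = motifs[ib],
             tf_a = g[ia], tf_b = g[ib],
             n11_cts = as.integer(n11c), n11_ubiq = as.integer(n11u),
             log_p_cts = log_p_cts, log_p_ubiq = log_p_ubiq,
             L = l_score(log_p_cts, log_p_ubiq),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag significant and ubiquitously co-occurring pairs by empirical quantiles
#'
#' Within one cell type, a pair is cell-type-specifically co-occurring when
#' its L strictly exceeds the upper empirical quantile (default 99.5%) of
#' all L scores of that cell type, and ubiquitously co-occurring when L is
#' strictly below the lower quantile (default 0.5%). Quantiles use linear
#' interpolation between order statistics. BH-adjusted q-values for both
#' strata are attached per cell type; they are reported alongside but do not
#' enter L.
#'
#' @param results data.frame from [score_all_pairs()] (one cell type).
#' @param upper_q,lower_q Quantile thresholds (defaults 0.995 and 0.005).
#' @return `results` with columns q_cts, q_ubiq, cts_significant,
#'   ubiq_cooccurring added.
#' @export
select_significant <- function(results, upper_q = 0.995, lower_q = 0.005) {
  if (NROW(results) == 0L) stop_("select_significant: empty results")
  if (!(lower_q > 0 && lower_q < upper_q && upper_q < 1))
    stop_("select_significant: need 0 < lower_q < upper_q < 1")
  if (length(unique(results$cell_type)) != 1L)
    stop_("select_significant: results must come from a single cell type")
  hi <- quantile(results$L, upper_q, names = FALSE)
  lo <- quantile(results$L, lower_q, names = FALSE)
  results$q_cts <- bh_adjust(exp(results$log_p_cts))
  results$q_ubiq <- bh_adjust(exp(results$log_p_ubiq))
  results$cts_significant <- results$L > hi
  results$ubiq_cooccurring <- results$L < lo
  results
}

#' Aggregate motif-pair results to TF-group pairs
#'
#' Significant motif pairs are assigned to their unordered TF-group pair;
#' per TF pair the best (maximum) L and smallest log p on the CTS stratum
#' are kept, and the pair is significant iff any constituent motif pair is.
#'
#' @param results Flagged data.frame from [select_significant()]; may span
#'   several cell types.
#' @param groups Unused placeholder kept for interface symmetry (group
#'   labels already travel with the results).
#' @return data.frame with one row per (cell_type, tf_a, tf_b): n_motif_pairs,
#'   L (max), log_p_cts (min), cts_significant, ubiq_cooccurring (any).
#' @export
aggregate_to_tf_pairs <- function(results, groups = NULL) {
  if (NROW(results) == 0L)
    return(data.frame(cell_type = character(), tf_a = character(),
                      tf_b = character(), n_motif_pairs = integer(),
                      L = numeric(), log_p_cts = numeric(),
                      cts_significant = logical(),
                      ubiq_cooccurring = logical(),
                      stringsAsFactors = FALSE))
  a <- pmin(results$tf_a, results$tf_b)
  b <- pmax(results$tf_a, results$tf_b)
  key <- paste(results$cell_type, a, b, sep = "\r")
  sp <- split(seq_len(nrow(results)), key)
  rows <- lapply(sp, function(i) {
    data.frame(cell_type = results$cell_type[i[1]],
               tf_a = a[i[1]], tf_b = b[i[1]],
               n_motif_pairs = length(i),
               L = max(results$L[i]),
               log_p_cts = min(results$log_p_cts[i]),
               cts_significant = any(results$cts_significant[i]),
               ubiq_cooccurring = any(results$ubiq_cooccurring[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell_type, out$tf_a, out$tf_b, method = "radix"), ,
      drop = FALSE]
}

#' Single-motif overrepresentation on cell-type-specific DHSs
#'
#' For each motif of one cell type, builds the bound/unbound x CTS/ubiq 2x2
#' table over the joint 2l stratum and tests enrichment of bound DHSs among
#' the CTS stratum with an upper-tail Fisher test. Motifs are ranked by
#' ascending p.
#'
#' @param calls A binding_calls object.
#' @param cell_type Cell type to analyze.
#' @param top Number of top motifs to flag in the `in_top` column
#'   (default 50, the size of the per-cell-type report).
#' @return data.frame ranked by log_p: cell_type, motif_id, n_bound_cts,
#'   n_bound_ubiq, log_p, rank, in_top.
#' @export
overrepresentation <- function(calls, cell_type, top = 50L) {
  if (!cell_type %in% names(calls$calls))
    stop_("overrepresentation: unknown cell type '%s'", cell_type)
  B <- calls$calls[[cell_type]]
  z <- calls$z[[cell_type]]
  l <- sum(z)
  n_bound_cts <- colSums(B[z, , drop = FALSE])
  n_bound_ubiq <- colSums(B[!z, , drop = FALSE])
  # margins: bound = k, CTS = l, total 2l
  log_p <- pmin(phyper(n_bound_cts - 1, m = n_bound_cts + n_bound_ubiq,
                       n = 2L * l - (n_bound_cts + n_bound_ubiq), k = l,
                       lower.tail = FALSE, log.p = TRUE), 0)
  out <- data.frame(cell_type = cell_type, motif_id = colnames(B),
                    n_bound_cts = as.integer(n_bound_cts),
                    n_bound_ubiq = as.integer(n_bound_ubiq),
                    log_p = log_p, stringsAsFactors = FALSE)
  out <- out[order(out$log_p, out$motif_id, method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$in_top <- out$rank <= top
  rownames(out) <- NULL
  out
}

#' Run the co-occurrence analysis for every cell type
#'
#' Convenience wrapper: [score_all_pairs()] + [select_significant()] per
#' cell type, rows bound together.
#'
#' @param calls A binding_calls object.
#' @param groups A motif_group_map.
#' @param upper_q,lower_q Passed to [select_significant()].
#' @return data.frame over all cell types with significance flags.
#' @export
score_cooccurrence <- function(calls, groups, upper_q = 0.995,
                               lower_q = 0.005) {
  out <- lapply(names(calls$calls), function(ct)
    select_significant(score_all_pairs(calls, groups, ct),
                       upper_q = upper_q, lower_q = lower_q))
  do.call(rbind, out)
}

#' Write pair results as TSV (S3-File-style layout)
#'
#' Columns: cell_type, tf_a, tf_b, motif_a, motif_b, n11_cts, n11_ubiq,
#' neg_log10_p_cts, neg_log10_p_ubiq, L, q_cts, q_ubiq, cts_significant,
#' ubiq_cooccurring. The two p-value columns are -log10 for readability;
#' L stays in natural-log units.
#'
#' @param results Flagged pair results.
#' @param path Output path.
#' @export
write_pair_results <- function(results, path) {
  out <- data.frame(cell_type = results$cell_type,
                    tf_a = results$tf_a, tf_b = results$tf_b,
                    motif_a = results$motif_a, motif_b = results$motif_b,
                    n11_cts = results$n11_cts, n11_ubiq = results$n11_ubiq,
                    neg_log10_p_cts = -results$log_p_cts / log(10),
                    neg_log10_p_ubiq = -results$log_p_ubiq / log(10),
                    L = results$L,
                    q_cts = results$q_cts, q_ubiq = results$q_ubiq,
                    cts_significant = results$cts_significant,
                    ubiq_cooccurring = results$ubiq_cooccurring,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
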