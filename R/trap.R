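# Biophysical (TRAP-style) binding affinity: a count matrix is turned into a
# mismatch-energy matrix; a sequence's affinity is the expected number of
# occupied sites, summing per-site occupancies r0*exp(-E)/(1+r0*exp(-E))
# over every position on both strands. No hit threshold is involved:
# low-affinity sites contribute proportionally.

#' Convert a motif count matrix to a mismatch-energy matrix
#'
#' Per position, base probabilities are estimated with a pseudocount and the
#' mismatch energy of base b is E_b = ln(p_max / p_b) / lambda, so the
#' consensus base has energy 0. The site-occupancy prefactor r0 defaults to
#' exp(0.584 * width - 5.66), which ties the binding constant to motif
#' length.
#'
#' @param motif A motif_matrix.
#' @param pseudocount Added to every base count (> 0; default 1).
#' @param lambda_ Energy scale (> 0; default 0.7).
#' @param r0 Optional prefactor override (> 0).
#' @return An `energy_matrix`: list(motif_id, width, energies, lambda_, r0)
#'   where energies is a width x 4 matrix over A,C,G,T with per-position
#'   minimum 0.
#' @export
energy_from_counts <- function(motif, pseudocount = 1, lambda_ = 0.7,
                               r0 = NULL) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop_("energy_from_counts: pseudocount must be > 0")
  if (!is.numeric(lambda_) || lambda_ <= 0)
    stop_("energy_from_counts: lambda_ must be > 0")
  cnt <- motif$counts
  p <- (cnt + pseudocount) / (rowSums(cnt) + 4 * pseudocount)
  E <- log(apply(p, 1L, max) / p) / lambda_
  colnames(E) <- DNA_BASES
  if (is.null(r0)) r0 <- exp(0.584 * motif$width - 5.66)
  if (r0 <= 0) stop_("energy_from_counts: r0 must be > 0")
  structure(list(motif_id = motif$motif_id, width = motif$width,
                 energies = E, lambda_ = lambda_, r0 = r0),
            class = "energy_matrix")
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("<energy_matrix %s: width %d, lambda %.3g, r0 %.3g>\n",
              x$motif_id, x$width, x$lambda_, x$r0))
  invisible(x)
}

# Summed site energies along one strand: E_site[i] = sum_j E[j, base[i+j-1]].
# `codes` indexes A,C,G,T = 1..4; anything else (N) is 5 and maps to +Inf
# energy, so sites containing N get zero occupancy.
site_energies <- function(codes, E) {
  n <- length(codes)
  w <- nrow(E)
  if (n < w) return(numeric(0))
  E5 <- cbind(E, Inf)  # 5th column: N / unknown base
  ns <- n - w + 1L
  esum <- numeric(ns)
  for (j in seq_len(w))
    esum <- esum + E5[j, codes[j:(j + ns - 1L)]]
  esum
}

#' TRAP affinity of a sequence for one motif
#'
#' Sums the occupancy r0*exp(-E)/(1 + r0*exp(-E)) of every length-w site on
#' both strands (the reverse strand is scored on the reverse complement).
#' Sites containing N contribute zero. A sequence shorter than the motif
#' scores 0.
#'
#' @param seq A DNA string over A,C,G,T,N (character scalar).
#' @param em An energy_matrix.
#' @return Non-negative affinity (expected occupied-site count).
#' @export
trap_affinity <- function(seq, em) {
  s <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  codes <- match(s, DNA_BASES)
  codes[is.na(codes)] <- 5L
  E <- em$energies
  # reverse strand: score the forward sequence with the reverse-complemented
  # energy matrix (row order reversed, A<->T and C<->G swapped)
  Erc <- E[rev(seq_len(nrow(E))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(Erc) <- DNA_BASES
  e_all <- c(site_energies(codes, E), site_energies(codes, Erc))
  if (!length(e_all)) return(0)
  x <- em$r0 * exp(-e_all)
  sum(x / (1 + x))
}

#' Affinity table over the selected DHSs of every cell type
#'
#' For each cell type the joint stratum is its l CTS windows followed by the
#' l ubiquitous windows; each of the 2l sequences is scored against every
#' motif. Ranking is always within this 2l-set, never genome-wide.
#'
#' @param selection A dhs_selection.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param motifs List of energy_matrix objects (or motif_matrix objects,
#'   which are converted with default parameters).
#' @return An `affinity_table`: list(tables = cell type -> 2l x n_motifs
#'   matrix, z = cell type -> logical CTS indicator, windows, l).
#' @export
score_dhs_set <- function(selection, genome, motifs) {
  motifs <- lapply(motifs, function(m)
    if (inherits(m, "energy_matrix")) m else energy_from_counts(m))
  ids_all <- unique(c(unlist(selection$cts, use.names = FALSE),
                      selection$ubiq))
  w <- selection$windows
  if (anyNA(match(ids_all, w$id)))
    stop_("score_dhs_set: unresolvable window id(s): %s",
          paste(head(setdiff(ids_all, w$id), 3), collapse = ", "))
  seqs <- window_sequences(w[match(ids_all, w$id), , drop = FALSE], genome)
  seq_chr <- as.character(seqs)
  aff_all <- vapply(motifs, function(em)
    vapply(seq_chr, trap_affinity, numeric(1), em = em),
    numeric(length(seq_chr)))
  if (is.null(dim(aff_all)))
    aff_all <- matrix(aff_all, nrow = length(seq_chr))
  rownames(aff_all) <- ids_all
  colnames(aff_all) <- vapply(motifs, `[[`, "", "motif_id")

  tables <- lapply(names(selection$cts), function(ct) {
    ids <- c(selection$cts[[ct]], selection$ubiq)
    aff_all[ids, , drop = FALSE]
  })
  names(tables) <- names(selection$cts)
  z <- lapply(tables, function(tab)
    rep(c(TRUE, FALSE), each = selection$l))
  structure(list(tables = tables, z = z, windows = w, l = selection$l),
            class = "affinity_table")
}

#' @export
print.affinity_table <- function(x, ...) {
  cat(sprintf("<affinity_table: %d cell types, 2l = %d DHSs x %d motifs>\n",
              length(x$tables), 2L * x$l, ncol(x$tables[[1]])))
  invisible(x)
}

#' Call bound/unbound DHSs from joint affinity rankings
#'
#' Per cell type and motif, the k DHSs with highest affinity within the
#' joint 2l stratum are "bound", all others "unbound". Ties at the boundary
#' are broken by genomic coordinate for reproducibility.
#'
#' @param affinity An affinity_table.
#' @param k Number of bound DHSs (atlas-scale default 1000 of 2l = 10000).
#' @return `binding_calls`: list(calls = cell type -> logical 2l x motifs
#'   matrix with exactly k TRUE per column, z, k, l, windows).
#' @export
call_bound <- function(affinity, k) {
  two_l <- 2L * affinity$l
  if (!is_count(k) || k < 1) stop_("call_bound: k must be a positive integer")
  if (k > two_l) stop_("call_bound: k = %d exceeds 2l = %d", k, two_l)
  w <- affinity$windows
  calls <- lapply(affinity$tables, function(tab) {
    coord <- match(rownames(tab), w$id)
    chrom <- w$chrom[coord]
    start <- w$start[coord]
    out <- matrix(FALSE, nrow(tab), ncol(tab),
                  dimnames = dimnames(tab))
    for (j in seq_len(ncol(tab))) {
      o <- order(-tab[, j], chrom, start, method = "radix")
      out[o[seq_len(k)], j] <- TRUE
    }
    out
  })
  structure(list(calls = calls, z = affinity$z, k = as.integer(k),
                 l = affinity$l, windows = affinity$windows),
            class = "binding_calls")
}

#' @export
print.binding_calls <- function(x, ...) {
  cat(sprintf("<binding_calls: k = %d of 2l = %d, %d cell types, %d motifs>\n",
              x$k, 2L * x$l, length(x$calls), ncol(x$calls[[1]])))
  invisible(x)
}
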