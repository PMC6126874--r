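# Log-space exact test machinery shared by the co-occurrence and
# overrepresentation analyses. p-values are carried as natural-log values
# end to end so extreme tables never underflow.

#' Natural-log upper-tail Fisher p-value of a 2x2 table
#'
#' Computes ln P(X >= n11) under the hypergeometric null with the table's
#' margins, exactly and in log space (no normal approximation), so tables
#' like [[1000,0],[0,1000]] yield a finite log p instead of 0.
#'
#' @param table A 2x2 matrix of non-negative counts
#'   \code{rbind(c(n11, n10), c(n01, n00))}, or a length-4 vector in that
#'   order.
#' @return ln p (<= 0). An all-zero table returns 0 (p = 1).
#' @export
log_fisher_upper <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4L) stop_("log_fisher_upper: expected a 2x2 table")
  if (anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop_("log_fisher_upper: counts must be non-negative integers")
  n11 <- x[1]; n10 <- if (is.matrix(table)) table[1, 2] else x[2]
  n01 <- if (is.matrix(table)) table[2, 1] else x[3]
  n00 <- if (is.matrix(table)) table[2, 2] else x[4]
  if (n11 + n10 + n01 + n00 == 0) return(0)
  # X ~ Hypergeometric(white = row1 margin, black = row2 margin,
  #                    drawn = column1 margin); upper tail P(X >= n11)
  lp <- phyper(n11 - 1, m = n11 + n10, n = n01 + n00, k = n11 + n01,
               lower.tail = FALSE, log.p = TRUE)
  min(lp, 0)
}

#' The L score contrasting cell-type-specific and ubiquitous co-binding
#'
#' L = -( ln p_cts - ln p_ubiq ) = ln p_ubiq - ln p_cts. Large positive L
#' means the pair co-occurs far more significantly on cell-type-specific
#' DHSs than on ubiquitously open DHSs; large negative L the reverse.
#'
#' @param log_p_cts,log_p_ubiq Natural-log upper-tail Fisher p-values
#'   (both <= 0).
#' @return The L score (natural log units).
#' @export
l_score <- function(log_p_cts, log_p_ubiq) {
  if (any(log_p_cts > 1e-12) || any(log_p_ubiq > 1e-12))
    stop_("l_score: log p-values must be <= 0")
  log_p_ubiq - log_p_cts
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving and capped at 1. Applied within
#' one cell type's family of tests.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop_("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
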