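# Shared fixtures and independent oracles built in code.

# Straight-line evaluation of the specificity t-statistic, written as plain
# loops over the defining formulas; independent of the vectorized
# implementation in the package.
oracle_t_statistic <- function(values, cell_types,
                               denominator = "sum") {
  cts <- sort(unique(cell_types))
  m <- length(cts)
  nw <- nrow(values)
  cell_means <- matrix(NA_real_, nw, m, dimnames = list(NULL, cts))
  for (w in seq_len(nw))
    for (j in seq_len(m))
      cell_means[w, j] <- mean(values[w, cell_types == cts[j]])
  global <- rowMeans(cell_means)
  s <- numeric(nw)
  df <- 0
  for (j in seq_len(m)) df <- df + sum(cell_types == cts[j]) - 1
  for (w in seq_len(nw)) {
    ss <- 0
    for (j in seq_len(m)) {
      idx <- which(cell_types == cts[j])
      if (length(idx) < 2) next
      ss <- ss + sum((values[w, idx] - cell_means[w, j])^2)
    }
    s[w] <- sqrt(ss / df)
  }
  s0 <- mean(s)
  t <- matrix(NA_real_, nw, m, dimnames = list(NULL, cts))
  for (w in seq_len(nw))
    for (j in seq_len(m)) {
      n_ct <- sum(cell_types == cts[j])
      t[w, j] <- if (denominator == "sum")
        (cell_means[w, j] - global[w]) /
          (sqrt(1 / m + 1 / n_ct) * (s[w] + s0[1]))
      else
        (cell_means[w, j] - global[w]) /
          sqrt((1 / m + 1 / n_ct) * (s[w] + s0[1]))
    }
  list(t = t, s = s, s0 = s0, cell_means = cell_means, global = global)
}

# Exhaustive hypergeometric upper-tail sum in log space (log-gamma +
# log-sum-exp); the independent oracle for log_fisher_upper.
oracle_log_tail <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10; r2 <- n01 + n00; c1 <- n11 + n01
  n <- r1 + r2
  hi <- min(r1, c1)
  if (n == 0 || n11 > hi) return(0)
  xs <- n11:hi
  lt <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  mx <- max(lt)
  mx + log(sum(exp(lt - mx)))
}

# Hand step-up Benjamini-Hochberg, written directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cur <- 1
  for (i in n:1) {
    cur <- min(cur, p[o[i]] * n / i)
    adj[o[i]] <- cur
  }
  pmin(adj, 1)
}

# A small log-stage count matrix from explicit values.
toy_log_matrix <- function(values, cell_types, width = 200L) {
  nw <- nrow(values)
  windows <- tile_genome(c(chrT = nw * width), width)
  samples <- load_sample_map(data.frame(
    sample_id = sprintf("s%02d", seq_along(cell_types)),
    cell_type = cell_types, stringsAsFactors = FALSE))
  count_matrix(windows, samples, values, stage = "log")
}

toy_raw_matrix <- function(values, cell_types, width = 200L) {
  nw <- nrow(values)
  windows <- tile_genome(c(chrT = nw * width), width)
  samples <- load_sample_map(data.frame(
    sample_id = sprintf("s%02d", seq_along(cell_types)),
    cell_type = cell_types, stringsAsFactors = FALSE))
  count_matrix(windows, samples, values, stage = "raw")
}

# Random motif count matrix for property tests.
random_motif <- function(width = 6L, id = "MX") {
  counts <- matrix(sample(0:20, width * 4L, replace = TRUE), width, 4L)
  counts[rowSums(counts) == 0, 1L] <- 1L
  colnames(counts) <- c("A", "C", "G", "T")
  cooctf:::new_motif_matrix(id, id, counts)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Unordered pair key used when comparing result sets.
pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# Minimal binding_calls object built directly from logical matrices, for
# unit tests of the statistics layer (bypasses sequence scoring).
manual_calls <- function(call_list, z_list, k, l, windows = NULL) {
  if (is.null(windows)) {
    n <- nrow(call_list[[1]])
    windows <- tile_genome(c(chrT = n * 200L), 200L)
  }
  structure(list(calls = call_list, z = z_list, k = as.integer(k),
                 l = as.integer(l), windows = windows),
            class = "binding_calls")
}
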