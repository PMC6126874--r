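test_that("pair tables stratify bound calls by the CTS indicator", {
  l <- 6L
  z <- rep(c(TRUE, FALSE), each = l)
  a <- z  # bound exactly on the CTS stratum
  pt <- build_pair_tables(a, a, z)
  expect_equal(pt$cts[1, 1], l)
  expect_equal(sum(pt$cts), l)
  expect_equal(pt$ubiq[2, 2], l)
  expect_equal(sum(pt$ubiq), l)

  expect_error(build_pair_tables(a[-1], a, z), "lengths differ")
  expect_error(build_pair_tables(a, a, rep(TRUE, 2 * l)), "exactly half")
})

test_that("swapping the motifs transposes each table and keeps n11", {
  set.seed(41)
  z <- rep(c(TRUE, FALSE), each = 50)
  a <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  b <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  ab <- build_pair_tables(a, b, z)
  ba <- build_pair_tables(b, a, z)
  expect_equal(ab$cts, t(ba$cts), ignore_attr = TRUE)
  expect_equal(ab$ubiq, t(ba$ubiq), ignore_attr = TRUE)
  expect_equal(ab$cts[1, 1], ba$cts[1, 1])
})

test_that("independent bound calls give near-uniform cells", {
  set.seed(42)
  l <- 400L
  z <- rep(c(TRUE, FALSE), each = l)
  k <- l  # k = l/2 per stratum on average: half the 2l DHSs bound
  a <- sample(rep(c(TRUE, FALSE), each = l))
  b <- sample(rep(c(TRUE, FALSE), each = l))
  pt <- build_pair_tables(a, b, z)
  # each cell of the CTS table ~ Binomial(l, 1/4): allow 4 sd
  tol <- 4 * sqrt(l * 0.25 * 0.75)
  expect_true(all(abs(as.vector(pt$cts) - l / 4) < tol))
})

make_toy_calls <- function(B1, z = NULL, k = NULL) {
  l <- nrow(B1) / 2L
  if (is.null(z)) z <- rep(c(TRUE, FALSE), each = l)
  if (is.null(k)) k <- max(colSums(B1))
  manual_calls(list(ct1 = B1), list(ct1 = z), k = k, l = l)
}

test_that("score_all_pairs enumerates exactly the cross-group pairs", {
  set.seed(43)
  B <- matrix(sample(c(TRUE, FALSE), 40 * 4, replace = TRUE), 40, 4,
              dimnames = list(NULL, c("m1", "m2", "m3", "m4")))
  calls <- make_toy_calls(B)
  groups <- load_motif_group_map(data.frame(
    motif_id = c("m1", "m2", "m3", "m4"),
    tf_group = c("A", "A", "B", "C")))
  res <- score_all_pairs(calls, groups, "ct1")
  expect_equal(nrow(res), 5L)  # C(4,2) minus the within-A pair
  expect_false(any(res$tf_a == res$tf_b))

  # all motifs in one group: nothing to test
  one <- load_motif_group_map(data.frame(
    motif_id = c("m1", "m2", "m3", "m4"), tf_group = "A"))
  expect_equal(nrow(score_all_pairs(calls, one, "ct1")), 0L)
})

test_that("score_all_pairs matches per-pair tables and log Fisher calls", {
  set.seed(44)
  B <- matrix(sample(c(TRUE, FALSE), 60 * 3, replace = TRUE), 60, 3,
              dimnames = list(NULL, c("m1", "m2", "m3")))
  calls <- make_toy_calls(B)
  groups <- load_motif_group_map(data.frame(
    motif_id = c("m1", "m2", "m3"), tf_group = c("A", "B", "C")))
  res <- score_all_pairs(calls, groups, "ct1")
  z <- calls$z$ct1
  for (r in seq_len(nrow(res))) {
    pt <- build_pair_tables(B[, res$motif_a[r]], B[, res$motif_b[r]], z)
    expect_equal(res$n11_cts[r], pt$cts[1, 1])
    expect_equal(res$n11_ubiq[r], pt$ubiq[1, 1])
    expect_equal(res$log_p_cts[r], log_fisher_upper(pt$cts),
                 tolerance = 1e-12)
    expect_equal(res$log_p_ubiq[r], log_fisher_upper(pt$ubiq),
                 tolerance = 1e-12)
    expect_equal(res$L[r], l_score(res$log_p_cts[r], res$log_p_ubiq[r]))
  }
})

test_that("quantile flags follow strict order-statistics rules", {
  res <- data.frame(cell_type = "ct1",
                    motif_a = sprintf("a%04d", 1:1000),
                    motif_b = sprintf("b%04d", 1:1000),
                    tf_a = "A", tf_b = "B",
                    n11_cts = 0L, n11_ubiq = 0L,
                    log_p_cts = -seq(0.001, 1, length.out = 1000),
                    log_p_ubiq = 0,
                    L = seq_len(1000) + 0.0,
                    stringsAsFactors = FALSE)
  fl <- select_significant(res)
  # 1000 distinct L values: exactly 5 above the 99.5% quantile and 5 below
  # the 0.5% quantile
  expect_equal(sum(fl$cts_significant), 5L)
  expect_equal(which(fl$cts_significant), 996:1000)
  expect_equal(sum(fl$ubiq_cooccurring), 5L)
  expect_equal(which(fl$ubiq_cooccurring), 1:5)

  # all-equal L: nothing passes a strict threshold
  res$L <- 1.0
  fl2 <- select_significant(res)
  expect_equal(sum(fl2$cts_significant), 0L)
  expect_equal(sum(fl2$ubiq_cooccurring), 0L)

  expect_error(select_significant(res[0, ]), "empty")
  expect_error(select_significant(res, upper_q = 0.4, lower_q = 0.5),
               "lower_q < upper_q")
})

test_that("BH q-values are attached per cell type and match the raw p order", {
  set.seed(45)
  res <- data.frame(cell_type = "ct1",
                    motif_a = sprintf("a%03d", 1:50),
                    motif_b = sprintf("b%03d", 1:50),
                    tf_a = "A", tf_b = "B", n11_cts = 0L, n11_ubiq = 0L,
                    log_p_cts = log(runif(50)), log_p_ubiq = log(runif(50)),
                    stringsAsFactors = FALSE)
  res$L <- res$log_p_ubiq - res$log_p_cts
  fl <- select_significant(res)
  expect_equal(fl$q_cts, oracle_bh(exp(res$log_p_cts)), tolerance = 1e-12)
  expect_true(all(fl$q_cts >= exp(res$log_p_cts) - 1e-15))
})

test_that("TF-pair aggregation applies the union rule", {
  res <- data.frame(
    cell_type = "ct1",
    motif_a = c("m1", "m2"), motif_b = c("m3", "m4"),
    tf_a = c("A", "A"), tf_b = c("B", "B"),
    n11_cts = 0L, n11_ubiq = 0L,
    log_p_cts = c(-9, -2), log_p_ubiq = c(-1, -1),
    L = c(8, 1), q_cts = 1, q_ubiq = 1,
    cts_significant = c(TRUE, FALSE), ubiq_cooccurring = FALSE,
    stringsAsFactors = FALSE)
  agg <- aggregate_to_tf_pairs(res)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$n_motif_pairs, 2L)
  expect_equal(agg$L, 8)               # max over constituent motif pairs
  expect_equal(agg$log_p_cts, -9)      # min over constituent motif pairs
  expect_true(agg$cts_significant)     # any constituent significant

  res$cts_significant <- FALSE
  agg2 <- aggregate_to_tf_pairs(res)
  expect_false(agg2$cts_significant)

  # unordered TF pair: (B,A) and (A,B) motif pairs land in one row
  res2 <- res
  res2$tf_a <- c("B", "A"); res2$tf_b <- c("A", "B")
  expect_equal(nrow(aggregate_to_tf_pairs(res2)), 1L)
})

test_that("TF-pair aggregation groups a larger fixture correctly", {
  set.seed(46)
  tfs <- rbind(c("A", "B"), c("A", "C"), c("B", "C"), c("C", "D"))
  pick <- sample(1:4, 10, replace = TRUE)
  res <- data.frame(
    cell_type = "ct1",
    motif_a = sprintf("ma%d", 1:10), motif_b = sprintf("mb%d", 1:10),
    tf_a = tfs[pick, 1], tf_b = tfs[pick, 2],
    n11_cts = 0L, n11_ubiq = 0L, log_p_cts = -runif(10),
    log_p_ubiq = -runif(10), L = rnorm(10), q_cts = 1, q_ubiq = 1,
    cts_significant = FALSE, ubiq_cooccurring = FALSE,
    stringsAsFactors = FALSE)
  agg <- aggregate_to_tf_pairs(res)
  expect_equal(nrow(agg), length(unique(pick)))
  for (r in seq_len(nrow(agg))) {
    i <- which(pick == which(tfs[, 1] == agg$tf_a[r] &
                               tfs[, 2] == agg$tf_b[r]))
    expect_equal(agg$n_motif_pairs[r], length(i))
    expect_equal(agg$L[r], max(res$L[i]))
  }
})

test_that("overrepresentation ranks motifs by CTS enrichment", {
  l <- 10L
  z <- rep(c(TRUE, FALSE), each = l)
  B <- cbind(all_cts = z,                         # bound on every CTS DHS
             balanced = rep(c(TRUE, FALSE), l))   # 5/5 in both strata
  calls <- make_toy_calls(B, k = 10L)
  ov <- overrepresentation(calls, "ct1", top = 1)
  expect_equal(ov$motif_id[1], "all_cts")
  # extreme table [[10,0],[0,10]]: minimal possible p for these margins
  expect_equal(ov$log_p[ov$motif_id == "all_cts"],
               log_fisher_upper(rbind(c(10, 0), c(0, 10))),
               tolerance = 1e-12)
  # balanced table [[5,5],[5,5]]: no direction of enrichment; the upper
  # tail sits at its central value (independence would give p = 1 under a
  # two-sided test)
  expect_equal(ov$log_p[ov$motif_id == "balanced"],
               oracle_log_tail(5, 5, 5, 5), tolerance = 1e-12)
  expect_gt(exp(ov$log_p[ov$motif_id == "balanced"]), 0.5)
  expect_equal(ov$in_top, c(TRUE, FALSE))
})
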