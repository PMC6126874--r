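test_that("t matches a straight-line evaluation of the defining formulas", {
  set.seed(11)
  vals <- matrix(runif(3 * 4, 0, 5), nrow = 3)
  ctypes <- c("a", "a", "b", "b")
  lm <- toy_log_matrix(vals, ctypes)
  res <- t_statistic(lm)
  ora <- oracle_t_statistic(vals, ctypes)
  expect_equal(unname(res$t), unname(ora$t), tolerance = 1e-12)
  expect_equal(unname(res$s), ora$s, tolerance = 1e-12)
  expect_equal(res$s0, ora$s0, tolerance = 1e-12)

  # and for the alternative radical placement
  res2 <- t_statistic(lm, denominator = "sqrt-inside")
  ora2 <- oracle_t_statistic(vals, ctypes, denominator = "sqrt-inside")
  expect_equal(unname(res2$t), unname(ora2$t), tolerance = 1e-12)
})

test_that("identical entries give t = 0 everywhere", {
  lm <- toy_log_matrix(matrix(2.5, 4, 6),
                       cell_types = rep(c("a", "b", "c"), each = 2))
  res <- t_statistic(lm)
  expect_true(all(res$t == 0))
})

test_that("t is invariant to swapping samples within a cell type", {
  set.seed(12)
  vals <- matrix(runif(5 * 4), 5, 4)
  lm1 <- toy_log_matrix(vals, c("a", "a", "b", "b"))
  lm2 <- toy_log_matrix(vals[, c(2, 1, 3, 4)], c("a", "a", "b", "b"))
  expect_equal(t_statistic(lm1)$t, t_statistic(lm2)$t)
})

test_that("t is invariant to adding a constant to every entry", {
  set.seed(13)
  vals <- matrix(runif(6 * 6, 0, 3), 6, 6)
  ctypes <- rep(c("a", "b", "c"), each = 2)
  t1 <- t_statistic(toy_log_matrix(vals, ctypes))$t
  t2 <- t_statistic(toy_log_matrix(vals + 1.7, ctypes))$t
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("cell-type deviations from the global mean sum to zero per window", {
  set.seed(14)
  vals <- matrix(runif(20 * 7, 0, 4), 20, 7)
  ctypes <- c("a", "a", "b", "b", "b", "c", "c")
  res <- t_statistic(toy_log_matrix(vals, ctypes))
  dev <- res$cell_means - res$global_mean
  expect_true(all(abs(rowSums(dev)) < 1e-9))
})

test_that("singleton cell types get t values but no variance contribution", {
  set.seed(15)
  vals <- matrix(runif(4 * 3), 4, 3)
  res <- t_statistic(toy_log_matrix(vals, c("a", "a", "solo")))
  expect_true(all(is.finite(res$t)))
  # pooled SD must equal the SD from the replicated cell type alone
  expect_equal(unname(res$s), apply(vals[, 1:2], 1, sd), tolerance = 1e-12)
})

test_that("degenerate designs are rejected", {
  vals <- matrix(runif(4 * 2), 4, 2)
  expect_error(t_statistic(toy_log_matrix(vals, c("a", "a"))),
               "at least 2 cell types")
  expect_error(t_statistic(toy_log_matrix(vals, c("a", "b"))),
               "single sample")
  raw <- toy_raw_matrix(matrix(1L, 2, 4), c("a", "a", "b", "b"))
  expect_error(t_statistic(raw), "log-stage")
})

test_that("select_cts returns top-l per cell type with coordinate ties", {
  # 4 windows, 2 cell types; windows 2 and 3 tie on t for cell type a
  vals <- rbind(c(1, 1, 1, 1),
                c(5, 3, 1, 1),
                c(5, 3, 1, 1),
                c(3, 1, 1, 1))
  lm <- toy_log_matrix(vals, c("a", "a", "b", "b"))
  res <- t_statistic(lm)
  expect_equal(res$t[2, "a"], res$t[3, "a"])
  top <- select_cts(res, 2)
  expect_equal(top$a, res$windows$id[2:3])  # tie -> lower coordinate first

  all4 <- select_cts(res, 4)
  expect_equal(sort(all4$a), sort(res$windows$id))
  expect_equal(all4$a[1:2], res$windows$id[2:3])  # still ordered by t
  expect_error(select_cts(res, 5), "exceeds")
})

test_that("select_ubiq applies the openness filter before ranking by |t|", {
  # 5 closed windows (all zero) and 5 open flat windows with tiny jitter
  vals <- rbind(matrix(0, 5, 4),
                matrix(5, 5, 4) + outer(1:5 * 1e-3, c(0, 1e-4, 0, 1e-4)))
  lm <- toy_log_matrix(vals, c("a", "a", "b", "b"))
  res <- t_statistic(lm)
  ub <- select_ubiq(res, 3, open_quantile = 0.5)
  expect_true(all(ub %in% res$windows$id[6:10]))
  expect_error(select_ubiq(res, 6, open_quantile = 0.5), "eligible")
})

test_that("flat-open windows are selected over specific ones", {
  # 50 flat-open windows and 50 cell-type-specific windows; l = 50 must
  # recover exactly the flat-open set
  set.seed(16)
  jit <- function(n, m) matrix(runif(n * m, -0.05, 0.05), n, m)
  flat <- matrix(8, 50, 4) + jit(50, 4)
  specific <- cbind(matrix(5, 50, 2), matrix(0.5, 50, 2)) + jit(50, 4)
  lm <- toy_log_matrix(rbind(flat, specific), c("a", "a", "b", "b"))
  res <- t_statistic(lm)
  ub <- select_ubiq(res, 50, open_quantile = 0.4)
  expect_setequal(ub, res$windows$id[1:50])
})

test_that("the elevated cell type always has the largest t in its window", {
  set.seed(17)
  for (rep in 1:10) {
    vals <- matrix(rnorm(30 * 6, mean = 3, sd = 0.2), 30, 6)
    vals[5, 3:4] <- vals[5, 3:4] + 4  # elevate cell type b in window 5
    res <- t_statistic(toy_log_matrix(vals, rep(c("a", "b", "c"), each = 2)))
    expect_equal(colnames(res$t)[which.max(res$t[5, ])], "b")
  }
})

test_that("characterize_dhs reports GC content and annotation overlap", {
  width <- 10L
  windows <- tile_genome(c(chrT = 100), width)
  samples <- load_sample_map(data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    cell_type = c("a", "a", "b", "b")))
  set.seed(18)
  vals <- matrix(runif(40, 1, 4), 10, 4)
  res <- t_statistic(count_matrix(windows, samples, vals, "log"))
  sel <- structure(list(cts = list(a = windows$id[1:2]),
                        ubiq = windows$id[3:4], l = 2L,
                        windows = windows),
                   class = "dhs_selection")
  genome <- Biostrings::DNAStringSet(c(
    chrT = paste0(strrep("GC", 10),          # windows 1-2: all G/C
                  strrep("AT", 10),          # windows 3-4: all A/T
                  strrep("A", 60))))
  ann <- list(promoter = data.frame(chrom = "chrT", start = 0, end = 15))
  out <- characterize_dhs(sel, genome, ann)
  expect_equal(out$mean_gc[out$set == "cts:a"], 1.0)
  expect_equal(out$mean_gc[out$set == "ubiq"], 0.0)
  # promoter [0,15) overlaps windows 1 and 2 -> fraction 1 for the CTS set
  expect_equal(out$frac_promoter[out$set == "cts:a"], 1.0)
  expect_equal(out$frac_promoter[out$set == "ubiq"], 0.0)

  # annotation equal to the windows themselves -> overlap fraction 1
  out2 <- characterize_dhs(sel, genome, list(self = windows))
  expect_true(all(out2$frac_self == 1.0))

  # window beyond the chromosome end errors
  sel$windows$end[1] <- 1000L
  sel$windows$start[1] <- 990L
  expect_error(characterize_dhs(sel, genome), "beyond")
})

test_that("partial annotation overlap gives the hand-counted fraction", {
  windows <- tile_genome(c(chrT = 100), 10)
  samples <- load_sample_map(data.frame(sample_id = c("s1", "s2"),
                                        cell_type = c("a", "b")))
  sel <- structure(list(cts = list(a = windows$id[1:10]),
                        ubiq = windows$id[1:10], l = 10L,
                        windows = windows),
                   class = "dhs_selection")
  genome <- Biostrings::DNAStringSet(c(chrT = random_dna(100)))
  # covers windows 1-4 only
  ann <- list(mark = data.frame(chrom = "chrT", start = 0, end = 40))
  out <- characterize_dhs(sel, genome, ann)
  expect_equal(out$frac_mark[out$set == "cts:a"], 0.4)
})
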