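# Seeded synthetic fixtures with the statistical structure the method
# assumes: a negative-binomial count matrix with planted cell-type-specific
# and ubiquitously open windows, and window sequences with planted
# co-occurring motif consensus sites. Ground truth travels with every
# object so recovery can be measured exactly.

# 12 built-in consensus words (width 8) over {A,C,G}: since every reverse
# complement contains T, no word collides with another word's reverse
# complement, keeping planted-site counts unambiguous.
DEFAULT_CONSENSUS <- c(
  M01 = "AACCGGCA", M02 = "ACGGCAAC", M03 = "AGCACGGA", M04 = "CAACGGAC",
  M05 = "CCGAAGCG", M06 = "CGACACGG", M07 = "GAAACCGC", M08 = "GACGCAAG",
  M09 = "GCCAGAAC", M10 = "GGACAACG", M11 = "GGCAGCAA", M12 = "CAGCGGAA")

DEFAULT_GROUPS <- c(
  M01 = "G1", M02 = "G1", M03 = "G2", M04 = "G2", M05 = "G3", M06 = "G3",
  M07 = "G4", M08 = "G4", M09 = "G5", M10 = "G6", M11 = "G7", M12 = "G8")

#' Build a sharp motif count matrix from a consensus word
#'
#' @param motif_id Motif id.
#' @param consensus DNA word over A/C/G/T.
#' @param weight Count given to the consensus base at each position
#'   (default 10; other bases get 0).
#' @return A motif_matrix.
#' @export
motif_from_consensus <- function(motif_id, consensus, weight = 10) {
  b <- strsplit(consensus, "", fixed = TRUE)[[1]]
  counts <- matrix(0, length(b), 4L, dimnames = list(NULL, DNA_BASES))
  counts[cbind(seq_along(b), match(b, DNA_BASES))] <- weight
  new_motif_matrix(motif_id, motif_id, counts)
}

#' Specification of a planted synthetic fixture
#'
#' Defines the study conditions of a synthetic multi-cell-type experiment:
#' window counts are negative-binomial (DNase-seq replicates are
#' overdispersed, and the t-statistic's s0 regularization only matters
#' under within-class variance); planted CTS windows are elevated only in
#' their cell type, planted ubiquitous windows in all; co-occurring motif
#' pairs are planted as consensus words in the CTS windows of their target
#' cell type (or in the ubiquitous windows for `ubiq_pairs`).
#'
#' @param n_windows Total genome windows (default 2000).
#' @param n_cell_types Cell types (default 4).
#' @param samples_per_cell_type Replicates per cell type (default 3).
#' @param window_width Window width in bp (default 200).
#' @param baseline_mean Expected read count of an open window (default 20).
#' @param closed_mean Expected count of a closed window (default 2).
#' @param specificity_effect Multiplicative elevation of planted windows
#'   (default 8; 1 gives the null fixture with no differential openness).
#' @param n_cts_per_type Planted CTS windows per cell type (default 50).
#' @param n_ubiq Planted ubiquitously open windows (default 50).
#' @param dispersion Negative-binomial size parameter (default 10).
#' @param motifs Named list of motif_matrix objects (default: 12 built-in
#'   consensus motifs).
#' @param groups motif_group_map for the motifs (default: 8 groups).
#' @param cooccur_pairs data.frame(motif_a, motif_b, cell_type, rate) of
#'   pairs planted in CTS windows; default one cross-group pair per cell
#'   type at rate 0.6.
#' @param ubiq_pairs data.frame(motif_a, motif_b, rate) planted in
#'   ubiquitous windows (default none).
#' @param background_motif_rate Per-window, per-motif probability of a
#'   stray singleton consensus insertion (default 0.05).
#' @param l,k,open_quantile Analysis settings matched to this fixture scale:
#'   stratum size l (default 50); bound cutoff k (default 40, chosen so the
#'   bound set can hold every planted occurrence of a motif, approximately
#'   rate * l + background occurrences); openness quantile (default 0.95,
#'   matched to the fixture's truly-open fraction of 250/2000 windows so
#'   the eligible set holds the open windows rather than closed-window
#'   noise). See the vignette.
#' @param seed Master seed; all randomness flows from it via a
#'   counter-based splitting scheme.
#' @return A validated `planted_spec` list.
#' @export
planted_spec <- function(n_windows = 2000L, n_cell_types = 4L,
                         samples_per_cell_type = 3L, window_width = 200L,
                         baseline_mean = 20, closed_mean = 2,
                         specificity_effect = 8, n_cts_per_type = 50L,
                         n_ubiq = 50L, dispersion = 10,
                         motifs = NULL, groups = NULL,
                         cooccur_pairs = NULL, ubiq_pairs = NULL,
                         background_motif_rate = 0.05,
                         l = 50L, k = 40L, open_quantile = 0.95,
                         seed = 1L) {
  if (is.null(motifs))
    motifs <- lapply(setNames(nm = names(DEFAULT_CONSENSUS)), function(id)
      motif_from_consensus(id, DEFAULT_CONSENSUS[[id]]))
  if (is.null(groups))
    groups <- load_motif_group_map(
      data.frame(motif_id = names(DEFAULT_GROUPS),
                 tf_group = unname(DEFAULT_GROUPS)))
  if (is.null(cooccur_pairs)) {
    pairs <- list(c("M01", "M03"), c("M05", "M07"),
                  c("M09", "M10"), c("M11", "M12"))
    nct <- min(n_cell_types, length(pairs))
    cooccur_pairs <- data.frame(
      motif_a = vapply(pairs[seq_len(nct)], `[`, "", 1L),
      motif_b = vapply(pairs[seq_len(nct)], `[`, "", 2L),
      cell_type = sprintf("ct%d", seq_len(nct)),
      rate = 0.6, stringsAsFactors = FALSE)
  }
  if (is.null(ubiq_pairs))
    ubiq_pairs <- data.frame(motif_a = character(), motif_b = character(),
                             rate = numeric(), stringsAsFactors = FALSE)
  spec <- structure(
    list(n_windows = as.integer(n_windows),
         n_cell_types = as.integer(n_cell_types),
         samples_per_cell_type = as.integer(samples_per_cell_type),
         window_width = as.integer(window_width),
         baseline_mean = baseline_mean, closed_mean = closed_mean,
         specificity_effect = specificity_effect,
         n_cts_per_type = as.integer(n_cts_per_type),
         n_ubiq = as.integer(n_ubiq), dispersion = dispersion,
         motifs = motifs, groups = groups,
         cooccur_pairs = cooccur_pairs, ubiq_pairs = ubiq_pairs,
         background_motif_rate = background_motif_rate,
         l = as.integer(l), k = as.integer(k),
         open_quantile = open_quantile, seed = as.integer(seed)),
    class = "planted_spec")
  validate_planted_spec(spec)
}

validate_planted_spec <- function(spec) {
  rates <- c(spec$cooccur_pairs$rate, spec$ubiq_pairs$rate,
             spec$background_motif_rate)
  if (any(rates < 0 | rates > 1))
    stop_("planted_spec: rates must lie in [0, 1]")
  if (spec$specificity_effect <= 0)
    stop_("planted_spec: specificity_effect must be > 0")
  planted <- spec$n_cts_per_type * spec$n_cell_types + spec$n_ubiq
  if (planted > spec$n_windows)
    stop_("planted_spec: %d planted windows exceed %d total windows",
          planted, spec$n_windows)
  widths <- vapply(spec$motifs, `[[`, 0L, "width")
  if (any(widths >= spec$window_width))
    stop_("planted_spec: motif width must be below window_width")
  bad <- setdiff(c(spec$cooccur_pairs$motif_a, spec$cooccur_pairs$motif_b,
                   spec$ubiq_pairs$motif_a, spec$ubiq_pairs$motif_b),
                 names(spec$motifs))
  if (length(bad))
    stop_("planted_spec: planted pair references unknown motif(s): %s",
          paste(bad, collapse = ", "))
  spec
}

#' @export
print.planted_spec <- function(x, ...) {
  cat(sprintf(
    "<planted_spec: %d windows x (%d cell types x %d samples), %d motifs, %d planted CTS pairs, seed %d>\n",
    x$n_windows, x$n_cell_types, x$samples_per_cell_type,
    length(x$motifs), nrow(x$cooccur_pairs), x$seed))
  invisible(x)
}

#' Simulate a raw count matrix with planted open windows
#'
#' Draws negative-binomial counts per window per sample. Closed windows
#' have mean `closed_mean` everywhere; planted CTS windows are open at
#' `baseline_mean` in all cell types and elevated to
#' `baseline_mean * specificity_effect` in their own; planted ubiquitous
#' windows sit at the elevated level in every cell type.
#'
#' @param spec A planted_spec.
#' @return list(counts = raw count_matrix, labels = data.frame(id, class)
#'   where class is "closed", "ubiq" or the planted cell type).
#' @export
simulate_count_matrix <- function(spec) {
  windows <- tile_genome(
    c(chrS = spec$n_windows * spec$window_width), spec$window_width)
  cts <- sprintf("ct%d", seq_len(spec$n_cell_types))
  samples <- load_sample_map(data.frame(
    sample_id = sprintf("%s_s%d", rep(cts, each = spec$samples_per_cell_type),
                        seq_len(spec$samples_per_cell_type)),
    cell_type = rep(cts, each = spec$samples_per_cell_type),
    stringsAsFactors = FALSE))
  with_seed(split_seed(spec$seed, 1L), {
    perm <- sample.int(spec$n_windows)
    class <- rep("closed", spec$n_windows)
    at <- 0L
    for (ct in cts) {
      class[perm[at + seq_len(spec$n_cts_per_type)]] <- ct
      at <- at + spec$n_cts_per_type
    }
    class[perm[at + seq_len(spec$n_ubiq)]] <- "ubiq"

    open <- spec$baseline_mean * spec$specificity_effect
    mu <- matrix(spec$closed_mean, spec$n_windows, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      ctj <- samples$cell_type[j]
      mu[class == "ubiq", j] <- open
      mu[class %in% cts, j] <- spec$baseline_mean
      mu[class == ctj, j] <- open
    }
    vals <- matrix(rnbinom(length(mu), size = spec$dispersion, mu = mu),
                   nrow = nrow(mu))
    list(counts = new_count_matrix(windows, samples, vals, "raw"),
         labels = data.frame(id = windows$id, class = class,
                             stringsAsFactors = FALSE))
  })
}

# Place a word into a sequence (1-based offset), returning the sequence.
plant_word <- function(seq, word, offset) {
  substr(seq, offset, offset + nchar(word) - 1L) <- word
  seq
}

#' Simulate window sequences with planted motif sites
#'
#' Background is i.i.d. uniform A/C/G/T. For every pair in
#' `spec$cooccur_pairs`, both motifs' consensus words are planted at
#' non-overlapping random offsets, with probability `rate`, in each CTS
#' window of the pair's target cell type; `spec$ubiq_pairs` are planted the
#' same way in ubiquitous windows. Independently, every motif is planted as
#' a stray singleton in any window with probability
#' `background_motif_rate`.
#'
#' @param spec A planted_spec.
#' @param labels Ground-truth window labels from [simulate_count_matrix()].
#' @return list(genome = one-chromosome [Biostrings::DNAStringSet]
#'   consistent with the tiling, sequences = named character vector per
#'   window, truth = data.frame(window_id, motif_id, offset, kind)).
#' @export
simulate_dhs_sequences <- function(spec, labels) {
  widths <- vapply(spec$motifs, `[[`, 0L, "width")
  w <- spec$window_width
  with_seed(split_seed(spec$seed, 2L), {
    seqs <- vapply(seq_len(nrow(labels)), function(i)
      paste(sample(DNA_BASES, w, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- labels$id
    truth <- list()

    # stray singleton background occurrences, overwritten later by planted
    # pairs if offsets collide
    for (mid in names(spec$motifs)) {
      hit <- which(runif(nrow(labels)) < spec$background_motif_rate)
      for (i in hit) {
        off <- sample.int(w - widths[[mid]] + 1L, 1L)
        seqs[i] <- plant_word(seqs[i], DEFAULT_WORD(spec, mid), off)
        truth[[length(truth) + 1L]] <- data.frame(
          window_id = labels$id[i], motif_id = mid, offset = off,
          kind = "background", stringsAsFactors = FALSE)
      }
    }

    plant_pair <- function(targets, ma, mb, rate, kind) {
      for (i in targets) {
        if (runif(1) >= rate) next
        wa <- widths[[ma]]; wb <- widths[[mb]]
        # draw non-overlapping offsets: a in the left half, b in the right
        oa <- sample.int(floor(w / 2) - wa + 1L, 1L)
        ob <- floor(w / 2) + sample.int(w - floor(w / 2) - wb + 1L, 1L)
        seqs[i] <<- plant_word(plant_word(seqs[i], DEFAULT_WORD(spec, ma),
                                          oa),
                               DEFAULT_WORD(spec, mb), ob)
        truth[[length(truth) + 1L]] <<- data.frame(
          window_id = rep(labels$id[i], 2L), motif_id = c(ma, mb),
          offset = c(oa, ob), kind = kind, stringsAsFactors = FALSE)
      }
    }
    cp <- spec$cooccur_pairs
    for (r in seq_len(nrow(cp)))
      plant_pair(which(labels$class == cp$cell_type[r]),
                 cp$motif_a[r], cp$motif_b[r], cp$rate[r], "cts_pair")
    up <- spec$ubiq_pairs
    for (r in seq_len(nrow(up)))
      plant_pair(which(labels$class == "ubiq"),
                 up$motif_a[r], up$motif_b[r], up$rate[r], "ubiq_pair")

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(window_id = character(), motif_id = character(),
                 offset = integer(), kind = character(),
                 stringsAsFactors = FALSE)
    genome <- Biostrings::DNAStringSet(
      setNames(paste(seqs, collapse = ""), "chrS"))
    list(genome = genome, sequences = seqs, truth = truth)
  })
}

DEFAULT_WORD <- function(spec, motif_id)
  motif_consensus(spec$motifs[[motif_id]])

#' Simulate a fixture and run the full analysis on it
#'
#' Convenience wrapper used for recovery experiments: generates the count
#' matrix and sequences from `spec`, then runs [run_analysis()] with the
#' fixture-scale settings carried by the spec (l, k, open_quantile).
#'
#' @param spec A planted_spec.
#' @return list(analysis = [run_analysis()] result, labels = ground-truth
#'   window labels, truth = planted-site table, spec).
#' @export
run_fixture <- function(spec) {
  sim <- simulate_count_matrix(spec)
  seqd <- simulate_dhs_sequences(spec, sim$labels)
  cfg <- run_config(window_width = spec$window_width, l = spec$l,
                    k = spec$k, open_quantile = spec$open_quantile,
                    seed = spec$seed)
  res <- run_analysis(sim$counts, seqd$genome, spec$motifs, spec$groups,
                      cfg)
  list(analysis = res, labels = sim$labels, truth = seqd$truth,
       spec = spec)
}

#' Build a complete on-disk fixture bundle
#'
#' Writes everything the pipeline consumes: the raw count matrix, sample
#' sheet, genome FASTA, TRANSFAC motif file, motif-group map, and a truth
#' JSON with the planted window labels and motif sites.
#'
#' @param spec A planted_spec.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of file paths plus the in-memory `bundle`.
#' @export
end_to_end_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_count_matrix(spec)
  seqdat <- simulate_dhs_sequences(spec, sim$labels)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genome = file.path(dir, "genome.fa"),
    motifs = file.path(dir, "motifs.transfac"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.json"))
  write_count_matrix(sim$counts, paths$counts)
  write.table(sim$counts$samples, paths$samples, sep = "\t", quote = FALSE,
              row.names = FALSE)
  Biostrings::writeXStringSet(seqdat$genome, paths$genome)
  write_transfac(spec$motifs, paths$motifs)
  write.table(data.frame(motif_id = names(spec$groups),
                         tf_group = unname(unclass(spec$groups))),
              paths$groups, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(labels = sim$labels, planted_sites = seqdat$truth,
         cooccur_pairs = spec$cooccur_pairs, ubiq_pairs = spec$ubiq_pairs,
         l = spec$l, k = spec$k, open_quantile = spec$open_quantile,
         seed = spec$seed),
    paths$truth, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(bundle = list(counts = sim$counts,
                                        labels = sim$labels,
                                        genome = seqdat$genome,
                                        sequences = seqdat$sequences,
                                        truth = seqdat$truth,
                                        spec = spec))))
}
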