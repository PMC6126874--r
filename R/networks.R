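# Cell-type-specific TF co-occurrence networks: assembly from flagged
# TF-pair summaries, pan-cell-type filtering, TF-centric co-factor queries,
# enrichment against external pair sets, and GraphML/SIF/TSV export.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Build per-cell-type TF networks and the cross-cell-type pair frequency
#'
#' One undirected network per cell type from its significant TF pairs
#' (nodes = TF groups, edges attributed with L and log_p_cts), plus a
#' frequency table counting in how many cell types each pair is significant.
#'
#' @param tf_pairs TF-pair summary data.frame from [aggregate_to_tf_pairs()]
#'   (may span several cell types; only `cts_significant` rows become edges).
#' @return A `tf_networks` list: networks (cell type -> igraph), freq
#'   (data.frame tf_a, tf_b, n_cell_types).
#' @export
build_networks <- function(tf_pairs) {
  sig <- tf_pairs[tf_pairs$cts_significant, , drop = FALSE]
  cts <- unique(tf_pairs$cell_type)
  networks <- lapply(cts, function(ct) {
    e <- sig[sig$cell_type == ct, , drop = FALSE]
    if (nrow(e) == 0L)
      return(igraph::make_empty_graph(0, directed = FALSE))
    igraph::graph_from_data_frame(
      data.frame(from = e$tf_a, to = e$tf_b, L = e$L,
                 log_p_cts = e$log_p_cts, cell_type = e$cell_type,
                 stringsAsFactors = FALSE),
      directed = FALSE)
  })
  names(networks) <- cts
  if (nrow(sig)) {
    key <- pair_key(sig$tf_a, sig$tf_b)
    cnt <- tapply(sig$cell_type, key, function(x) length(unique(x)))
    parts <- do.call(rbind, strsplit(names(cnt), "|", fixed = TRUE))
    freq <- data.frame(tf_a = parts[, 1], tf_b = parts[, 2],
                       n_cell_types = as.integer(cnt),
                       stringsAsFactors = FALSE, row.names = NULL)
  } else {
    freq <- data.frame(tf_a = character(), tf_b = character(),
                       n_cell_types = integer(), stringsAsFactors = FALSE)
  }
  structure(list(networks = networks, freq = freq), class = "tf_networks")
}

#' @export
print.tf_networks <- function(x, ...) {
  ec <- vapply(x$networks, igraph::ecount, numeric(1))
  cat(sprintf("<tf_networks: %d cell types, %d distinct significant pairs, %d edges total>\n",
              length(x$networks), nrow(x$freq), sum(ec)))
  invisible(x)
}

#' Remove pan-cell-type TF pairs from a network
#'
#' Drops edges whose pair is significant in `max_freq` or more cell types
#' (default 30) and then removes isolated nodes, leaving the cell-type-
#' specific part of the network.
#'
#' @param network An igraph network from [build_networks()].
#' @param freq Pair frequency table covering all edges.
#' @param max_freq Removal threshold (default 30 cell types).
#' @return The filtered igraph.
#' @export
filter_common <- function(network, freq, max_freq = 30L) {
  if (igraph::ecount(network) == 0L) return(network)
  el <- igraph::as_edgelist(network)
  key <- pair_key(el[, 1], el[, 2])
  f <- freq$n_cell_types[match(key, pair_key(freq$tf_a, freq$tf_b))]
  f[is.na(f)] <- 0L
  out <- igraph::delete_edges(network, which(f >= max_freq))
  igraph::delete_vertices(out, which(igraph::degree(out) == 0))
}

#' Co-factor profile of one TF across cell types
#'
#' Lists every TF significantly co-occurring with the query TF in at least
#' one cell type, with the supporting cell types and their count (the
#' edge-weight semantics of a TF-centric network).
#'
#' @param tf Query TF group id.
#' @param tf_pairs TF-pair summary data.frame (all cell types).
#' @param groups motif_group_map used to validate the query TF.
#' @return data.frame: partner, n_cell_types, cell_types (comma-joined),
#'   best_L; ordered by descending support.
#' @export
cofactor_profile <- function(tf, tf_pairs, groups) {
  if (!tf %in% unclass(groups))
    stop_("cofactor_profile: unknown TF group '%s'", tf)
  sig <- tf_pairs[tf_pairs$cts_significant &
                    (tf_pairs$tf_a == tf | tf_pairs$tf_b == tf), ,
                  drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(partner = character(), n_cell_types = integer(),
                      cell_types = character(), best_L = numeric(),
                      stringsAsFactors = FALSE))
  partner <- ifelse(sig$tf_a == tf, sig$tf_b, sig$tf_a)
  sp <- split(seq_len(nrow(sig)), partner)
  out <- do.call(rbind, lapply(names(sp), function(p) {
    i <- sp[[p]]
    cts <- sort(unique(sig$cell_type[i]))
    data.frame(partner = p, n_cell_types = length(cts),
               cell_types = paste(cts, collapse = ","),
               best_L = max(sig$L[i]), stringsAsFactors = FALSE)
  }))
  out[order(-out$n_cell_types, out$partner, method = "radix"), ,
      drop = FALSE]
}

#' Enrichment of a predicted pair set in a reference pair set
#'
#' 2x2 membership table over a universe of testable TF pairs (e.g. predicted
#' co-occurring pairs vs. experimentally supported protein-protein
#' interactions), with odds ratio and upper-tail Fisher log p.
#'
#' @param predicted,reference Character vectors of pair keys (any consistent
#'   encoding; use [tf_pair_keys()] to build "A|B" keys), both subsets of
#'   `universe`.
#' @param universe All testable pair keys.
#' @return list(table, odds_ratio, log_p, p).
#' @export
pairset_enrichment <- function(predicted, reference, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_("pairset_enrichment: empty universe")
  predicted <- unique(predicted); reference <- unique(reference)
  if (length(setdiff(predicted, universe)))
    stop_("pairset_enrichment: predicted pairs outside the universe")
  if (length(setdiff(reference, universe)))
    stop_("pairset_enrichment: reference pairs outside the universe")
  inP <- universe %in% predicted
  inR <- universe %in% reference
  tab <- matrix(c(sum(inP & inR), sum(inP & !inR),
                  sum(!inP & inR), sum(!inP & !inR)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(predicted = c("yes", "no"),
                                reference = c("yes", "no")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  lp <- log_fisher_upper(tab)
  list(table = tab, odds_ratio = or, log_p = lp, p = exp(lp))
}

#' Canonical unordered pair keys "A|B"
#' @param a,b Character vectors of TF ids.
#' @export
tf_pair_keys <- function(a, b) pair_key(a, b)

#' Export a TF network as GraphML, SIF or TSV
#'
#' GraphML keeps node and edge attributes (lossless round trip via
#' [igraph::read_graph()]); SIF carries topology only ("A cooccur B"); TSV
#' writes the attributed edge list.
#'
#' @param network An igraph network.
#' @param path Output path.
#' @param format One of "graphml", "sif", "tsv".
#' @export
export_network <- function(network, path, format = c("graphml", "sif",
                                                     "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else if (format == "sif") {
    if (igraph::ecount(network) == 0L) {
      writeLines(character(0), path)
    } else {
      el <- igraph::as_edgelist(network)
      writeLines(sprintf("%s\tcooccur\t%s", el[, 1], el[, 2]), path)
    }
  } else {
    el <- if (igraph::ecount(network)) igraph::as_data_frame(network) else
      data.frame(from = character(), to = character())
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
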