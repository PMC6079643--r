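#' Network centrality table
#'
#' Computes, for every gene of a connected network, the four connectivity
#' measures used to prioritise candidate regulators: degree (number of direct
#' neighbours), betweenness (number of shortest paths passing through the
#' gene, unnormalised and unweighted), farness (total shortest-path distance
#' to all other genes) with its standard inverse closeness `(n-1)/farness`,
#' and average neighbour degree. Betweenness and closeness are additionally
#' ranked from highest to lowest (rank 1 = most central; for closeness that is
#' the smallest total distance); ties share the minimum rank.
#'
#' @param net A connected `igraph` (apply [largest_subnetwork()] first).
#' @return Data frame with columns `gene`, `degree`, `betweenness`, `farness`,
#'   `closeness`, `avg_neighbor_degree`, `betweenness_rank`, `closeness_rank`.
#' @export
centralities <- function(net) {
  if (!igraph::is_connected(net)) {
    stop("network is disconnected; apply largest_subnetwork() first")
  }
  n <- igraph::vcount(net)
  genes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, weights = NA)
  dmat <- igraph::distances(net, weights = NA)
  farness <- rowSums(dmat)
  closeness <- if (n > 1) (n - 1) / farness else rep(NA_real_, n)
  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  annd <- as.numeric(adj %*% deg) / deg
  data.frame(gene = genes,
             degree = as.integer(deg),
             betweenness = as.numeric(btw),
             farness = as.integer(farness),
             closeness = closeness,
             avg_neighbor_degree = annd,
             betweenness_rank = as.integer(rank(-btw, ties.method = "min")),
             closeness_rank = as.integer(rank(-closeness, ties.method = "min")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Order genes by a centrality measure
#'
#' @param table A centrality table from [centralities()].
#' @param by One of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"avg_neighbor_degree"`.
#' @return Character vector of gene IDs, descending in the measure; ties are
#'   broken by lexicographic gene ID so the order is deterministic.
#' @export
rank_table <- function(table, by = c("degree", "betweenness", "closeness",
                                     "avg_neighbor_degree")) {
  by <- match.arg(by)
  table$gene[order(-table[[by]], table$gene)]
}
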