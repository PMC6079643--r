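# edges at or above a (possibly raised) CLR threshold; never below the build
# threshold, since discarded edges cannot be recovered from the graph
thresholded_graph <- function(net, threshold) {
  built <- igraph::graph_attr(net, "clr_threshold")
  if (!is.null(built) && is.finite(built) && threshold < built) {
    stop(sprintf("threshold %.3g is below the network's build threshold %.3g; re-filtering is upward only",
                 threshold, built))
  }
  keep <- igraph::E(net)[igraph::E(net)$clr_score >= threshold]
  igraph::subgraph_from_edges(net, keep, delete.vertices = FALSE)
}

first_order_neighbors <- function(g, seed) {
  igraph::V(g)$name[as.integer(igraph::neighbors(g, seed))]
}

#' First-order neighbourhood of seed genes
#'
#' Extracts the subgraph spanned by the seed genes and every gene directly
#' linked to a seed by an edge at or above the threshold. Seeds are part of
#' their own neighbourhood; edge signs are kept. Seeds absent from the
#' network are reported via a warning (an error if none is present).
#'
#' @param net An `igraph` from [build_network()].
#' @param seeds Character vector of seed gene IDs.
#' @param threshold CLR threshold (`>=` the network's build threshold).
#' @return Node-induced `igraph` subgraph; absent seeds are recorded in the
#'   `absent_seeds` graph attribute.
#' @export
neighborhood <- function(net, seeds,
                         threshold = igraph::graph_attr(net, "clr_threshold")) {
  present <- intersect(seeds, igraph::V(net)$name)
  absent <- setdiff(seeds, present)
  if (!length(present)) {
    stop("none of the seed genes is present in the network: ",
         paste(seeds, collapse = ", "))
  }
  if (length(absent)) {
    warning("seed gene(s) absent from the network: ",
            paste(absent, collapse = ", "))
  }
  g <- thresholded_graph(net, threshold)
  nodes <- unique(c(present, unlist(lapply(present, function(s) {
    first_order_neighbors(g, s)
  }))))
  sub <- igraph::induced_subgraph(g, nodes)
  igraph::set_graph_attr(sub, "absent_seeds", absent)
}

#' One-step neighbourhood expansion
#'
#' Adds to the current gene set every first-order neighbour (at or above the
#' threshold) of any member. One step per call; iterate for multi-step
#' expansion. Output always contains the input.
#'
#' @param net An `igraph` from [build_network()].
#' @param current Non-empty character vector of gene IDs.
#' @param threshold Expansion CLR threshold.
#' @return Character vector: `current` plus its first-order neighbours.
#' @export
expand_neighborhood <- function(net, current,
                                threshold = igraph::graph_attr(net, "clr_threshold")) {
  if (!length(current)) stop("'current' gene set is empty")
  g <- thresholded_graph(net, threshold)
  present <- intersect(current, igraph::V(g)$name)
  nb <- unlist(lapply(present, function(s) first_order_neighbors(g, s)))
  union(current, nb)
}

#' Restrict a gene set to annotated transcription factors
#'
#' @param genes Character vector of gene IDs (order preserved).
#' @param annotation Data frame with columns `gene_id` and logical `is_tf`.
#' @return The TF-flagged subset of `genes`; may be empty.
#' @export
tf_subset <- function(genes, annotation) {
  if (!all(c("gene_id", "is_tf") %in% names(annotation))) {
    stop("'annotation' needs columns gene_id and is_tf")
  }
  tfs <- annotation$gene_id[as.logical(annotation$is_tf)]
  genes[genes %in% tfs]
}

#' Probe membership in a seed's neighbourhood
#'
#' Presence/absence readout: is each probe gene a first-order neighbour of the
#' seed at the given threshold? Probes missing from the network are reported
#' as absent-from-network, distinct from a plain `FALSE`. The seed itself is a
#' member of its own neighbourhood by convention and is flagged.
#'
#' @param net An `igraph` from [build_network()].
#' @param seed Seed gene ID (must be in the network).
#' @param probes Character vector of probe gene IDs.
#' @param threshold CLR threshold.
#' @return Data frame: `probe`, `in_network`, `in_neighborhood` (`NA` when the
#'   probe is not in the network), `is_seed`.
#' @export
neighborhood_membership <- function(net, seed, probes,
                                    threshold = igraph::graph_attr(net, "clr_threshold")) {
  if (!seed %in% igraph::V(net)$name) {
    stop(sprintf("seed gene '%s' is not in the network", seed))
  }
  g <- thresholded_graph(net, threshold)
  nb <- c(seed, first_order_neighbors(g, seed))
  in_net <- probes %in% igraph::V(net)$name
  data.frame(probe = probes,
             in_network = in_net,
             in_neighborhood = ifelse(in_net, probes %in% nb, NA),
             is_seed = probes == seed,
             stringsAsFactors = FALSE)
}

#' Cross-species neighbourhood-conservation test
#'
#' Quantifies whether a seed gene's co-expression neighbourhood is conserved
#' between two species linked by an ortholog map. The published readout is
#' qualitative (are key genes present in all neighbourhoods?); the
#' hypergeometric overlap statistic computed here is this package's own
#' quantification of that readout.
#'
#' For seed `a` in network A with first-order neighbours `N_A` at
#' `threshold_a`: each ortholog `b` of `a` present in network B is a candidate
#' seed. A neighbour `n` of `a` counts as conserved when ANY of its orthologs
#' lies in `b`'s neighbourhood at `threshold_b` (family semantics;
#' `mode = "best"` keeps only the first listed ortholog per gene). Neighbours
#' with no ortholog in network B are excluded from the denominator. The
#' p-value is the hypergeometric upper tail of the overlap, with the universe
#' restricted to network-B genes that have an A-ortholog. The best (smallest
#' p) candidate seed is reported; the verdict is `conserved` when
#' `p <= alpha`, `diverged` otherwise, and `untestable` when the seed has no
#' ortholog in network B or no mapped neighbour exists.
#'
#' @param net_a,net_b `igraph` networks for the two species.
#' @param orthologs Data frame with columns `gene_a`, `gene_b` (many-to-many
#'   allowed).
#' @param seed_a Seed gene ID in network A.
#' @param threshold_a,threshold_b CLR thresholds for the two networks.
#' @param alpha Significance level for the conserved verdict.
#' @param mode `"any"` (family semantics, default) or `"best"` (first listed
#'   ortholog only).
#' @return One-row data frame: `seed_a`, `seed_b`, `n_neighbors_a`,
#'   `n_mapped`, `overlap`, `overlap_fraction`, `p_value`, `verdict`,
#'   `found`, `missing` (semicolon-collapsed neighbour lists).
#' @export
conservation_test <- function(net_a, net_b, orthologs, seed_a,
                              threshold_a = igraph::graph_attr(net_a, "clr_threshold"),
                              threshold_b = igraph::graph_attr(net_b, "clr_threshold"),
                              alpha = 0.05, mode = c("any", "best")) {
  mode <- match.arg(mode)
  if (!all(c("gene_a", "gene_b") %in% names(orthologs))) {
    stop("'orthologs' needs columns gene_a and gene_b")
  }
  if (!seed_a %in% igraph::V(net_a)$name) {
    stop(sprintf("seed gene '%s' is not in network A", seed_a))
  }
  omap <- orthologs[, c("gene_a", "gene_b")]
  if (mode == "best") omap <- omap[!duplicated(omap$gene_a), , drop = FALSE]

  ga <- thresholded_graph(net_a, threshold_a)
  n_a <- setdiff(first_order_neighbors(ga, seed_a), seed_a)

  empty_row <- function(verdict, seed_b = NA_character_) {
    data.frame(seed_a = seed_a, seed_b = seed_b,
               n_neighbors_a = length(n_a), n_mapped = 0L, overlap = 0L,
               overlap_fraction = NA_real_, p_value = NA_real_,
               verdict = verdict, found = "", missing = "",
               stringsAsFactors = FALSE)
  }
  b_names <- igraph::V(net_b)$name
  seed_b_cands <- intersect(omap$gene_b[omap$gene_a == seed_a], b_names)
  if (!length(seed_b_cands)) return(empty_row("untestable"))

  universe <- intersect(unique(omap$gene_b), b_names)
  gb <- thresholded_graph(net_b, threshold_b)

  best <- NULL
  for (sb in seed_b_cands) {
    nb_b <- setdiff(first_order_neighbors(gb, sb), sb)
    uni <- setdiff(universe, sb)
    white <- intersect(nb_b, uni)
    orth_of <- function(gene) intersect(omap$gene_b[omap$gene_a == gene], uni)
    mapped <- n_a[vapply(n_a, function(n) length(orth_of(n)) > 0, logical(1))]
    conserved <- mapped[vapply(mapped, function(n) {
      length(intersect(orth_of(n), white)) > 0
    }, logical(1))]
    if (!length(mapped)) {
      row <- empty_row("untestable", sb)
    } else {
      p <- stats::phyper(length(conserved) - 1, length(white),
                         length(uni) - length(white), length(mapped),
                         lower.tail = FALSE)
      row <- data.frame(seed_a = seed_a, seed_b = sb,
                        n_neighbors_a = length(n_a),
                        n_mapped = length(mapped),
                        overlap = length(conserved),
                        overlap_fraction = length(conserved) / length(mapped),
                        p_value = p,
                        verdict = if (p <= alpha) "conserved" else "diverged",
                        found = paste(conserved, collapse = ";"),
                        missing = paste(setdiff(mapped, conserved), collapse = ";"),
                        stringsAsFactors = FALSE)
    }
    if (is.null(best) ||
        (!is.na(row$p_value) && (is.na(best$p_value) || row$p_value < best$p_value))) {
      best <- row
    }
  }
  best
}

#' Conservation report over several seed genes
#'
#' Runs [conservation_test()] for each seed and binds the rows.
#'
#' @inheritParams conservation_test
#' @param seeds Character vector of seed gene IDs in network A.
#' @param ... Passed to [conservation_test()].
#' @return Data frame with one row per seed.
#' @export
conservation_report <- function(net_a, net_b, orthologs, seeds, ...) {
  do.call(rbind, lapply(seeds, function(s) {
    conservation_test(net_a, net_b, orthologs, s, ...)
  }))
}
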