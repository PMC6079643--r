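#' Gene-set collection
#'
#' Bundles a named list of gene sets (GO-style terms, planted synthetic sets,
#' TF families, ...) with the gene universe against which enrichment is
#' tested. Sets are restricted to the universe; terms left empty after the
#' restriction are dropped.
#'
#' @param sets Named list of character vectors of gene IDs.
#' @param universe Character vector: all genes eligible for testing
#'   (typically the expressed genes).
#' @param descriptions Optional named character vector of term descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("'sets' must be a uniquely named list")
  }
  universe <- unique(as.character(universe))
  restricted <- lapply(sets, function(g) intersect(unique(g), universe))
  keep <- lengths(restricted) > 0
  restricted <- restricted[keep]
  desc <- stats::setNames(rep("", length(restricted)), names(restricted))
  if (!is.null(descriptions)) {
    hit <- intersect(names(descriptions), names(desc))
    desc[hit] <- descriptions[hit]
  }
  structure(list(sets = restricted, universe = universe, descriptions = desc),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Fisher / hypergeometric gene-set enrichment
#'
#' One-sided over-representation test per term: with a universe of `U` genes,
#' a term of `t` genes and a query of `q` genes sharing `k` genes with the
#' term, the p-value is the hypergeometric upper tail `P(X >= k)`, identical
#' to the one-sided Fisher exact test on the 2x2 table. Benjamini-Hochberg
#' q-values are computed across all terms tested for this query.
#'
#' @param query Character vector of gene IDs; genes outside the universe are
#'   dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @return Data frame sorted by p-value: `term`, `description`, `set_size`
#'   (query size after restriction), `term_size`, `overlap`, `p_value`,
#'   `fdr_q`.
#' @export
fisher_enrichment <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- intersect(query, collection$universe)
  }
  if (!length(query)) stop("query is empty after restriction to the universe")
  u <- length(collection$universe)
  q <- length(query)
  res <- do.call(rbind, lapply(names(collection$sets), function(term) {
    tg <- collection$sets[[term]]
    k <- length(intersect(query, tg))
    p <- stats::phyper(k - 1, length(tg), u - length(tg), q, lower.tail = FALSE)
    data.frame(term = term,
               description = unname(collection$descriptions[term]),
               set_size = q, term_size = length(tg), overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  }))
  res$fdr_q <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$term), , drop = FALSE]
}

#' Enrichment per expression cluster
#'
#' Applies [fisher_enrichment()] to each flat cluster of a clustering result,
#' with the collection's universe (all expressed genes) as background.
#'
#' @param result A `cluster_result` from [cluster_genes()].
#' @param collection A [gene_set_collection()].
#' @return Named list of enrichment tables, one per cluster label.
#' @export
enrich_clusters <- function(result, collection) {
  stopifnot(inherits(result, "cluster_result"))
  labs <- sort(unique(result$gene_labels))
  out <- lapply(labs, function(l) {
    fisher_enrichment(names(result$gene_labels)[result$gene_labels == l],
                      collection)
  })
  names(out) <- as.character(labs)
  out
}

#' Enrichment per sample expression domain
#'
#' For one replicate tree (the series do not align exactly across trees, so a
#' single tree is analysed), tests each sample's domain gene set -- the genes
#' whose expression peaks at that sample -- for term over-representation.
#' Samples with no assigned genes are skipped with a message.
#'
#' @param domains A `domain_assignment` from [assign_expression_domain()].
#' @param collection A [gene_set_collection()].
#' @param tree Tree identifier to analyse.
#' @return Named list of enrichment tables, one per (non-empty) sample.
#' @export
enrich_domains <- function(domains, collection, tree) {
  stopifnot(inherits(domains, "domain_assignment"))
  meta <- domains$sample_meta
  if (!tree %in% meta$tree) {
    stop(sprintf("unknown tree '%s'; available: %s", tree,
                 paste(unique(meta$tree), collapse = ", ")))
  }
  samples <- meta$sample_id[meta$tree == tree]
  out <- list()
  for (s in samples) {
    genes <- names(domains$assignments)[vapply(domains$assignments,
                                               function(a) s %in% a, logical(1))]
    genes <- intersect(genes, collection$universe)
    if (!length(genes)) {
      message(sprintf("sample %s has no assigned genes; skipped", s))
      next
    }
    out[[s]] <- fisher_enrichment(genes, collection)
  }
  out
}
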