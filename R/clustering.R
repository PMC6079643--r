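#' Variance filter ahead of clustering
#'
#' Keeps genes whose expression varies enough across all samples to carry a
#' developmental profile. The published rule "variance of sigma > 1" conflates
#' the variance and its square root, so both readings are implemented: the
#' default interprets the cutoff as a variance (`var > min_sigma`), the
#' alternative as a standard deviation (`sd > min_sigma`). At the default
#' cutoff of 1 the two coincide.
#'
#' @param vst A `section_series` with `value_kind = "vst"`.
#' @param min_sigma Cutoff (strict `>`).
#' @param interpretation `"variance"` (default) or `"sd"`.
#' @return Character vector of kept gene IDs, input order preserved.
#' @export
variance_filter <- function(vst, min_sigma = 1,
                            interpretation = c("variance", "sd")) {
  stopifnot(inherits(vst, "section_series"))
  if (vst$value_kind != "vst") stop("variance_filter expects a vst matrix")
  interpretation <- match.arg(interpretation)
  if (ncol(vst$values) < 2) stop("variance undefined with a single sample")
  v <- apply(vst$values, 1, stats::var)
  cut <- if (interpretation == "variance") min_sigma else min_sigma^2
  gene_ids(vst)[v > cut]
}

#' Ward hierarchical clustering of genes and samples
#'
#' Clusters genes on Pearson-correlation distance `1 - r` and samples on
#' Euclidean distance over the gene-filtered matrix, both with Ward linkage
#' applied directly to the precomputed distances (as classic expression
#' heatmap tooling does). The gene dendrogram is cut into `k` flat clusters;
#' the matrix scaled per gene (z-scores) is returned for display.
#'
#' @param vst A `section_series` with `value_kind = "vst"`.
#' @param genes Genes to include (e.g. the [variance_filter()] survivors);
#'   `NULL` for all.
#' @param k Number of flat clusters to cut.
#' @return A `cluster_result` list: `gene_labels` (named integer vector),
#'   `gene_dendrogram`, `sample_dendrogram` (hclust objects), `scaled_matrix`,
#'   `k`, `included_genes`.
#' @export
cluster_genes <- function(vst, genes = NULL, k) {
  stopifnot(inherits(vst, "section_series"))
  if (is.null(genes)) genes <- gene_ids(vst)
  xm <- subset_series(vst, genes = genes)$values
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (k > nrow(xm)) stop("'k' exceeds the number of genes")
  const <- apply(xm, 1, function(r) stats::sd(r) == 0)
  if (any(const)) {
    stop("correlation undefined for constant gene(s): ",
         paste(rownames(xm)[const], collapse = ", "))
  }
  gd <- stats::as.dist(1 - stats::cor(t(xm)))
  gh <- stats::hclust(gd, method = "ward.D")
  sh <- stats::hclust(stats::dist(t(xm)), method = "ward.D")
  labels <- stats::cutree(gh, k = k)
  scaled <- scale_rows(xm)
  structure(list(gene_labels = labels,
                 gene_dendrogram = gh,
                 sample_dendrogram = sh,
                 scaled_matrix = scaled,
                 k = as.integer(k),
                 included_genes = rownames(xm)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d genes in %d clusters\n",
              length(x$gene_labels), x$k))
  print(table(x$gene_labels))
  invisible(x)
}

scale_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  (m - mu) / sd
}

#' Per-gene z-scaling
#'
#' Standardises each gene profile to mean 0 and SD 1 (the scaling used for
#' expression heatmaps where values above the gene average read as one colour
#' and below as the other).
#'
#' @param vst A `section_series`.
#' @param genes Genes to scale; `NULL` for all.
#' @return Numeric matrix of z-scores.
#' @export
scale_per_gene <- function(vst, genes = NULL) {
  stopifnot(inherits(vst, "section_series"))
  if (is.null(genes)) genes <- gene_ids(vst)
  m <- subset_series(vst, genes = genes)$values
  sd <- apply(m, 1, stats::sd)
  if (any(sd == 0)) {
    stop("cannot scale constant gene(s): ",
         paste(rownames(m)[sd == 0], collapse = ", "))
  }
  scale_rows(m)
}

#' Expression-domain assignment
#'
#' Assigns every gene to the sample(s) in which it is expressed within a
#' multiplicative tolerance of its maximum across all samples:
#' sample `s` is assigned when `x[g, s] >= (1 - tolerance) * max_s x[g, s]`
#' (inclusive). Genes whose maximum is not positive have no meaningful
#' domain and are skipped; they are reported in `skipped`.
#'
#' @param vst A `section_series`.
#' @param tolerance Fraction of the maximum allowed below it; default 0.04,
#'   must lie in `[0, 1)`.
#' @return A `domain_assignment` list: `assignments` (named list of sample ID
#'   vectors), `tolerance`, `sample_meta`, `skipped`.
#' @export
assign_expression_domain <- function(vst, tolerance = 0.04) {
  stopifnot(inherits(vst, "section_series"))
  if (!is.numeric(tolerance) || length(tolerance) != 1 ||
      tolerance < 0 || tolerance >= 1) {
    stop("'tolerance' must lie in [0, 1)")
  }
  m <- vst$values
  mx <- apply(m, 1, max)
  ok <- mx > 0
  sids <- sample_ids(vst)
  assignments <- lapply(which(ok), function(i) {
    sids[m[i, ] >= (1 - tolerance) * mx[i]]
  })
  names(assignments) <- gene_ids(vst)[ok]
  structure(list(assignments = assignments,
                 tolerance = tolerance,
                 sample_meta = vst$sample_meta,
                 skipped = gene_ids(vst)[!ok]),
            class = "domain_assignment")
}
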