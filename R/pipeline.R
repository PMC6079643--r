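#' Pipeline configuration
#'
#' Collects every stage's parameters with the analysis defaults: expression
#' filter `VST > 3` in `>= 2` samples per tree in `>= 2` trees; network
#' threshold `CLR >= 5` with `3.5` as the lower alternate and `5` for
#' neighbourhood expansion; variance filter `> 1`; 7 flat clusters (six
#' developmental clusters plus the noise pool); domain tolerance 4% of the
#' per-gene maximum; FDR 0.05. Unknown keys are rejected by name.
#'
#' @param ... Overrides of the defaults listed above (see source for the full
#'   key list: `vst_threshold`, `min_samples_per_tree`, `min_trees`,
#'   `clr_threshold`, `alt_threshold`, `expansion_threshold`,
#'   `threshold_scan`, `min_sigma`, `sigma_interpretation`, `n_clusters`,
#'   `domain_tolerance`, `fdr_alpha`, `mi_bins`, `mi_scheme`, `domain_tree`,
#'   `rng_seed`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    vst_threshold = 3,
    min_samples_per_tree = 2,
    min_trees = 2,
    clr_threshold = 5,
    alt_threshold = 3.5,
    expansion_threshold = 5,
    threshold_scan = NULL,
    min_sigma = 1,
    sigma_interpretation = "variance",
    n_clusters = 7,
    domain_tolerance = 0.04,
    fdr_alpha = 0.05,
    mi_bins = NULL,
    mi_scheme = "equal_frequency",
    domain_tree = "T1",
    rng_seed = 1)
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) && is.list(args[[1]])) {
    args <- args[[1]]
  }
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, args, keep.null = TRUE)
  num_pos <- c("vst_threshold", "min_samples_per_tree", "min_trees",
               "clr_threshold", "alt_threshold", "expansion_threshold",
               "min_sigma", "n_clusters")
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 ||
        !is.finite(cfg[[k]]) || cfg[[k]] <= 0) {
      stop(sprintf("invalid '%s': must be a positive number", k))
    }
  }
  if (cfg$domain_tolerance < 0 || cfg$domain_tolerance >= 1) {
    stop("invalid 'domain_tolerance': must be in [0, 1)")
  }
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) {
    stop("invalid 'fdr_alpha': must be in (0, 1)")
  }
  if (!cfg$sigma_interpretation %in% c("variance", "sd")) {
    stop("invalid 'sigma_interpretation': must be 'variance' or 'sd'")
  }
  if (!cfg$mi_scheme %in% c("equal_frequency", "equal_width", "bspline")) {
    stop("invalid 'mi_scheme'")
  }
  if (!is.null(cfg$threshold_scan) &&
      (!is.numeric(cfg$threshold_scan) || length(cfg$threshold_scan) < 1)) {
    stop("invalid 'threshold_scan': must be a numeric vector of candidates")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat `key: value` YAML; unknown keys are rejected with the offending key
#' named.
#'
#' @param path File path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Chains every stage over a raw count series: normalisation and variance
#' stabilisation, the expression filter, MI/CLR network inference with either
#' a fixed threshold or a scale-freeness scan, the largest connected
#' sub-network and its centralities, variance filtering plus Ward clustering
#' and expression domains, per-cluster and per-sample enrichment, and -- when
#' a second species' matrix and an ortholog map are supplied -- the
#' cross-species conservation report. Every stage writes a TSV into the run
#' directory, and a machine-readable JSON log records parameters, the seed
#' and all row/edge counts. Identical configuration and inputs give identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param inputs List with `expression` (a `section_series` of counts or a
#'   TSV path) and optionally `gene_sets` (a [gene_set_collection()] or GMT
#'   path), `annotation` (data frame or TSV path with `gene_id`, `is_tf`),
#'   `expression_b`, `orthologs`, `seeds` for the comparative stage.
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with the main stage results (`vst`, `expressed`,
#'   `threshold`, `network`, `subnetwork`, `centrality`, `clusters`,
#'   `domains`, `cluster_enrichment`, `domain_enrichment`, `conservation`,
#'   `log`).
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs$expression)) stop("inputs$expression is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)

  load_series <- function(x, kind = "counts") {
    if (inherits(x, "section_series")) return(x)
    if (!file.exists(x)) stop("missing input path: ", x)
    read_expression_tsv(x, kind)
  }
  counts <- load_series(inputs$expression)
  log <- list(config = unclass(config),
              n_genes_input = nrow(counts$values),
              n_samples = ncol(counts$values))

  sf <- compute_size_factors(counts)
  vst <- vst_transform(counts, sf)
  expressed <- filter_expressed(vst, config$vst_threshold,
                                config$min_samples_per_tree, config$min_trees)
  log$n_expressed <- length(expressed)
  vst_f <- subset_series(vst, genes = expressed)
  write_expression_tsv(vst_f, file.path(out_dir, "vst_expressed.tsv"))

  mi <- mutual_information(vst_f, bins = config$mi_bins,
                           scheme = config$mi_scheme)
  clr <- clr_transform(mi)
  if (!is.null(config$threshold_scan)) {
    sel <- select_threshold_scale_free(clr, config$threshold_scan)
    threshold <- sel$threshold
    log$threshold_scan <- sel$report
    utils::write.table(sel$report, file.path(out_dir, "threshold_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    threshold <- config$clr_threshold
  }
  log$clr_threshold <- threshold
  net <- build_network(vst_f, clr, threshold)
  log$n_edges <- igraph::ecount(net)
  write_network(net, file.path(out_dir, "network_edges.tsv"))

  sub <- largest_subnetwork(net)
  log$n_subnetwork_genes <- igraph::vcount(sub)
  cent <- centralities(sub)
  utils::write.table(cent, file.path(out_dir, "centrality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_graphml(sub, file.path(out_dir, "subnetwork.graphml"), cent)

  varkept <- variance_filter(vst_f, config$min_sigma,
                             config$sigma_interpretation)
  log$n_variance_filtered <- length(varkept)
  clusters <- NULL
  if (length(varkept) >= config$n_clusters) {
    clusters <- cluster_genes(vst_f, varkept, k = config$n_clusters)
    utils::write.table(
      data.frame(gene_id = names(clusters$gene_labels),
                 cluster = clusters$gene_labels),
      file.path(out_dir, "gene_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  domains <- assign_expression_domain(vst_f, config$domain_tolerance)
  dom_df <- data.frame(gene_id = names(domains$assignments),
                       samples = vapply(domains$assignments, paste,
                                        character(1), collapse = ","))
  utils::write.table(dom_df, file.path(out_dir, "expression_domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cluster_enrichment <- NULL
  domain_enrichment <- NULL
  if (!is.null(inputs$gene_sets)) {
    collection <- if (inherits(inputs$gene_sets, "gene_set_collection")) {
      gene_set_collection(inputs$gene_sets$sets, expressed,
                          inputs$gene_sets$descriptions)
    } else {
      read_gmt(inputs$gene_sets, universe = expressed)
    }
    if (!is.null(clusters)) {
      cluster_enrichment <- enrich_clusters(clusters, collection)
      ce <- do.call(rbind, Map(function(tab, cl) {
        cbind(cluster = cl, tab)
      }, cluster_enrichment, names(cluster_enrichment)))
      utils::write.table(ce, file.path(out_dir, "cluster_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (config$domain_tree %in% counts$sample_meta$tree) {
      domain_enrichment <- enrich_domains(domains, collection,
                                          config$domain_tree)
      de <- do.call(rbind, Map(function(tab, s) {
        cbind(sample = s, tab)
      }, domain_enrichment, names(domain_enrichment)))
      utils::write.table(de, file.path(out_dir, "domain_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  conservation <- NULL
  if (!is.null(inputs$expression_b) && !is.null(inputs$orthologs) &&
      !is.null(inputs$seeds)) {
    counts_b <- load_series(inputs$expression_b)
    vst_b <- vst_transform(counts_b)
    expressed_b <- filter_expressed(vst_b, config$vst_threshold,
                                    config$min_samples_per_tree,
                                    config$min_trees)
    vst_bf <- subset_series(vst_b, genes = expressed_b)
    clr_b <- clr_transform(mutual_information(vst_bf, bins = config$mi_bins,
                                              scheme = config$mi_scheme))
    net_b <- build_network(vst_bf, clr_b, config$alt_threshold)
    orth <- if (is.data.frame(inputs$orthologs)) inputs$orthologs else {
      read_orthologs(inputs$orthologs)
    }
    net_a_low <- build_network(vst_f, clr, min(threshold, config$alt_threshold))
    conservation <- conservation_report(
      net_a_low, net_b, orth, inputs$seeds,
      threshold_a = threshold, threshold_b = config$alt_threshold,
      alpha = config$fdr_alpha)
    write_report(conservation, file.path(out_dir, "conservation_report"))
    log$n_conserved <- sum(conservation$verdict == "conserved")
    log$n_diverged <- sum(conservation$verdict == "diverged")
  }

  log$package_version <- as.character(utils::packageVersion("xylemnet"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(list(vst = vst_f, expressed = expressed, threshold = threshold,
                 network = net, subnetwork = sub, centrality = cent,
                 clusters = clusters, domains = domains,
                 cluster_enrichment = cluster_enrichment,
                 domain_enrichment = domain_enrichment,
                 conservation = conservation, log = log))
}
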