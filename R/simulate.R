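#' Configuration for the cryosection-series simulator
#'
#' Collects and validates every knob of the synthetic-data generator. The
#' defaults emulate the sampling design the analysis assumes: three replicate
#' trees, each cut into 14-18 pooled tangential sections spanning the
#' developmental axis from cambium through expanding xylem, secondary-cell-wall
#' formation and cell death to mature xylem/latewood, with six "real" gene
#' clusters peaking at successive positions plus a pool of profile-less noise
#' genes.
#'
#' @param n_genes Total number of genes.
#' @param n_clusters Number of real (peaked) clusters; a noise pool labelled
#'   `"z"` is added on top of these.
#' @param n_trees Number of replicate trees.
#' @param samples_per_tree Integer vector of length `n_trees`; if `NULL`, each
#'   tree's sample count is drawn uniformly from 14-18 when simulating.
#' @param peak_positions Per-cluster peak position, strictly inside (0, 1)
#'   along the developmental axis; default evenly spaced.
#' @param peak_width SD of the Gaussian expression bump on the axis.
#' @param expression_base Baseline mean count for every gene.
#' @param amplitude Height of the expression bump, on the count-mean scale
#'   (default 8x the baseline).
#' @param nb_dispersion Negative binomial dispersion `alpha`
#'   (variance = mu + alpha * mu^2), shared by all genes.
#' @param noise_gene_fraction Fraction of genes with position-independent mean.
#' @param tf_fraction Fraction of genes labelled as transcription factors.
#' @param n_terms Number of gene sets generated per cluster.
#' @param library_size_cv Coefficient of variation of per-sample library-size
#'   factors (log-normal, mean 1).
#' @param missing_sample Optional `list(tree =, position =)`; that sample is
#'   blanked from the output to exercise imputation.
#' @param rng_seed Integer seed; all randomness flows from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 600,
                              n_clusters = 6,
                              n_trees = 3,
                              samples_per_tree = NULL,
                              peak_positions = NULL,
                              peak_width = 0.07,
                              expression_base = 50,
                              amplitude = 8 * expression_base,
                              nb_dispersion = 0.1,
                              noise_gene_fraction = 0.25,
                              tf_fraction = 0.1,
                              n_terms = 2,
                              library_size_cv = 0.2,
                              missing_sample = NULL,
                              rng_seed = 1) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
        x != round(x)) {
      stop(sprintf("invalid '%s': must be a positive integer", nm))
    }
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      stop(sprintf("invalid '%s': must be a positive real", nm))
    }
  }
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
      stop(sprintf("invalid '%s': must be in [0, 1]", nm))
    }
  }
  chk_count(n_genes, "n_genes")
  chk_count(n_clusters, "n_clusters")
  chk_count(n_trees, "n_trees")
  if (!is.null(samples_per_tree)) {
    if (length(samples_per_tree) != n_trees) {
      stop("invalid 'samples_per_tree': length must equal n_trees")
    }
    for (s in samples_per_tree) chk_count(s, "samples_per_tree")
    if (any(samples_per_tree < 2)) {
      stop("invalid 'samples_per_tree': need at least 2 samples per tree")
    }
    samples_per_tree <- as.integer(samples_per_tree)
  }
  if (is.null(peak_positions)) {
    peak_positions <- seq(0.08, 0.92, length.out = n_clusters)
  }
  if (length(peak_positions) != n_clusters ||
      any(!is.finite(peak_positions)) ||
      any(peak_positions <= 0) || any(peak_positions >= 1)) {
    stop("invalid 'peak_positions': need one value per cluster, strictly inside (0, 1)")
  }
  chk_pos(peak_width, "peak_width")
  chk_pos(expression_base, "expression_base")
  if (!is.numeric(amplitude) || length(amplitude) != 1 || !is.finite(amplitude) ||
      amplitude < 0) {
    stop("invalid 'amplitude': must be a non-negative real")
  }
  chk_pos(nb_dispersion, "nb_dispersion")
  chk_frac(noise_gene_fraction, "noise_gene_fraction")
  chk_frac(tf_fraction, "tf_fraction")
  chk_count(n_terms, "n_terms")
  if (!is.numeric(library_size_cv) || length(library_size_cv) != 1 ||
      !is.finite(library_size_cv) || library_size_cv < 0) {
    stop("invalid 'library_size_cv': must be a non-negative real")
  }
  if (!is.null(missing_sample) &&
      (!is.list(missing_sample) ||
       !all(c("tree", "position") %in% names(missing_sample)))) {
    stop("invalid 'missing_sample': must be list(tree =, position =)")
  }
  if (!is.numeric(rng_seed) || length(rng_seed) != 1 || !is.finite(rng_seed) ||
      rng_seed != round(rng_seed)) {
    stop("invalid 'rng_seed': must be an integer")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 n_trees = as.integer(n_trees),
                 samples_per_tree = samples_per_tree,
                 peak_positions = as.numeric(peak_positions),
                 peak_width = peak_width,
                 expression_base = expression_base,
                 amplitude = amplitude,
                 nb_dispersion = nb_dispersion,
                 noise_gene_fraction = noise_gene_fraction,
                 tf_fraction = tf_fraction,
                 n_terms = as.integer(n_terms),
                 library_size_cv = library_size_cv,
                 missing_sample = missing_sample,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

# log-normal library-size factors with mean 1 and the requested CV
rlibsize <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

build_sample_frame <- function(spt) {
  trees <- paste0("T", seq_along(spt))
  do.call(rbind, lapply(seq_along(spt), function(t) {
    data.frame(sample_id = sprintf("%s:%02d", trees[t], seq_len(spt[t])),
               tree = trees[t],
               position = seq_len(spt[t]),
               x = (seq_len(spt[t]) - 1) / (spt[t] - 1),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a cryosection expression series with planted clusters
#'
#' Generates a gene x sample negative binomial count matrix in which each
#' non-noise gene's expected profile is a Gaussian bump
#' `base + amplitude * exp(-(x - peak)^2 / (2 w^2))` along the developmental
#' axis (position `x` of sample `s` in tree `t` is `(rank - 1)/(n_t - 1)`),
#' scaled by a per-sample library-size factor. Noise genes have a
#' position-independent mean. Alongside the matrix, the planted ground truth
#' (cluster labels, TF flags, cluster-linked gene sets) is returned so that
#' downstream stages can be scored against it.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `matrix` (a `section_series` of counts) and
#'   `truth` (list: `cluster_label` named character vector with noise genes
#'   labelled `"z"`, `tf_genes`, `gene_sets` named list of gene vectors,
#'   `set_cluster` named character vector mapping each term to its cluster,
#'   `peak_positions`, `gene_peak`, `library_size`).
#' @export
simulate_series <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  spt <- config$samples_per_tree
  if (is.null(spt)) spt <- sample(14:18, config$n_trees, replace = TRUE)
  samples <- build_sample_frame(spt)
  n_s <- nrow(samples)

  n_g <- config$n_genes
  gid <- sprintf("G%04d", seq_len(n_g))
  n_noise <- round(config$noise_gene_fraction * n_g)
  labels <- c(rep("z", n_noise),
              rep(letters[seq_len(config$n_clusters)],
                  length.out = n_g - n_noise))
  labels <- sample(labels)            # shuffle assignment over gene IDs
  names(labels) <- gid

  peak <- rep(NA_real_, n_g)
  names(peak) <- gid
  for (k in seq_len(config$n_clusters)) {
    peak[labels == letters[k]] <- config$peak_positions[k]
  }
  amp <- stats::runif(n_g, 0.8, 1.2) * config$amplitude
  amp[labels == "z"] <- 0

  lib <- rlibsize(n_s, config$library_size_cv)
  names(lib) <- samples$sample_id

  bump <- outer(peak, samples$x, function(p, x) {
    ifelse(is.na(p), 0, exp(-(x - p)^2 / (2 * config$peak_width^2)))
  })
  mu <- (config$expression_base + amp * bump) %*% diag(lib)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / config$nb_dispersion),
                   nrow = n_g, dimnames = list(gid, samples$sample_id))

  tf_genes <- sort(sample(gid, round(config$tf_fraction * n_g)))

  gene_sets <- list()
  set_cluster <- character(0)
  for (k in seq_len(config$n_clusters)) {
    members <- gid[labels == letters[k]]
    if (!length(members)) next
    for (j in seq_len(config$n_terms)) {
      core <- sample(members, max(1, round(0.6 * length(members))))
      contam <- sample(setdiff(gid, members),
                       max(0, round(0.03 * n_g)))
      nm <- sprintf("SET_%s_%d", letters[k], j)
      gene_sets[[nm]] <- sort(unique(c(core, contam)))
      set_cluster[nm] <- letters[k]
    }
  }

  meta <- samples[, c("sample_id", "tree", "position")]
  mat <- section_series(counts, meta, "counts")
  if (!is.null(config$missing_sample)) {
    mat <- drop_sample(mat, config$missing_sample$tree,
                       config$missing_sample$position)
    lib <- lib[sample_ids(mat)]
  }
  truth <- list(cluster_label = labels,
                tf_genes = tf_genes,
                gene_sets = gene_sets,
                set_cluster = set_cluster,
                peak_positions = config$peak_positions,
                gene_peak = peak,
                library_size = lib)
  list(matrix = mat, truth = truth)
}

#' Simulate a two-species regulatory-module pair
#'
#' Generates expression matrices for two pseudo-species sharing a set of
#' regulatory modules: in species A each seed hub and its targets co-vary
#' around a shared Gaussian-bump latent profile (plus independent negative
#' binomial noise); species B mirrors this through a 1:1 ortholog map except
#' for `n_diverged` seeds, whose B-side targets are replaced by an unrelated
#' gene set (the original targets become profile-less). This plants the
#' conserved/diverged scenario that the cross-species conservation test is
#' meant to recover.
#'
#' @param config A [simulation_config()]; `n_genes`, the tree/sample layout,
#'   `expression_base`, `amplitude`, `nb_dispersion`, `library_size_cv` and
#'   `rng_seed` are used.
#' @param n_seeds Number of seed hubs.
#' @param n_targets_per_seed Targets co-regulated with each seed; a single
#'   integer or a vector of length `n_seeds` (regulon sizes in real networks
#'   are heterogeneous, and a spread of module sizes is what gives the
#'   thresholded graph its heavy-tailed degree distribution).
#' @param n_diverged Number of seeds rewired in species B (`<= n_seeds`).
#' @param missing_ortholog_fraction Fraction of non-module genes dropped from
#'   the ortholog map (seeds and targets always remain mapped).
#' @return List with `matrix_a`, `matrix_b` (count `section_series`), and
#'   `truth` (list: `seeds` data frame with columns `seed_a`, `seed_b`,
#'   `diverged`; `targets_a`, `targets_b` named lists per seed;
#'   `module_edges` data frame of truly co-regulated pairs in species A;
#'   `orthologs` data frame `gene_a`, `gene_b`, `family_id`).
#' @export
simulate_species_pair <- function(config,
                                  n_seeds = 5,
                                  n_targets_per_seed = 8,
                                  n_diverged = 1,
                                  missing_ortholog_fraction = 0) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.numeric(n_diverged) || n_diverged < 0 || n_diverged != round(n_diverged)) {
    stop("invalid 'n_diverged': must be a non-negative integer")
  }
  if (n_diverged > n_seeds) {
    stop("invalid 'n_diverged': cannot exceed n_seeds")
  }
  if (missing_ortholog_fraction < 0 || missing_ortholog_fraction >= 1) {
    stop("invalid 'missing_ortholog_fraction': must be in [0, 1)")
  }
  if (!length(n_targets_per_seed) %in% c(1L, n_seeds)) {
    stop("invalid 'n_targets_per_seed': must have length 1 or n_seeds")
  }
  n_targets <- rep_len(as.integer(n_targets_per_seed), n_seeds)
  module_size <- n_seeds + sum(n_targets)
  need <- module_size + sum(n_targets[seq_len(n_seeds)] * 0) +
    if (n_diverged > 0) max(n_targets) * n_diverged else 0
  if (config$n_genes < need + 10) {
    stop(sprintf("n_genes too small: need at least %d genes", need + 10))
  }
  set.seed(config$rng_seed)
  spt <- config$samples_per_tree
  if (is.null(spt)) spt <- sample(14:18, config$n_trees, replace = TRUE)
  samples <- build_sample_frame(spt)
  n_s <- nrow(samples)
  n_g <- config$n_genes

  idx <- seq_len(n_g)
  base_ids <- sprintf("G%04d", idx)
  ids_a <- paste0("A_", base_ids)
  ids_b <- paste0("B_", base_ids)

  seed_idx <- seq_len(n_seeds)
  target_idx <- split(n_seeds + seq_len(sum(n_targets)),
                      rep(seq_len(n_seeds), times = n_targets))
  background <- setdiff(idx, c(seed_idx, unlist(target_idx)))
  diverged <- if (n_diverged > 0) sort(sample(seq_len(n_seeds), n_diverged)) else integer(0)
  # replacement target sets for diverged seeds, disjoint, drawn from background
  repl_pool <- sample(background, sum(n_targets[diverged]))
  repl_idx <- if (n_diverged > 0) {
    split(repl_pool, rep(seq_along(diverged), times = n_targets[diverged]))
  } else list()

  latent_pos <- seq(0.1, 0.9, length.out = n_seeds)

  module_mu <- function(member_of) {
    # member_of: integer vector over genes, 0 = background, else seed index
    m <- matrix(config$expression_base, n_g, n_s)
    for (k in seq_len(n_seeds)) {
      rows <- which(member_of == k)
      if (!length(rows)) next
      prof <- exp(-(samples$x - latent_pos[k])^2 / (2 * config$peak_width^2))
      ampk <- stats::runif(length(rows), 0.8, 1.2) * config$amplitude
      m[rows, ] <- config$expression_base + ampk %o% prof
    }
    m
  }

  member_a <- integer(n_g)
  member_a[seed_idx] <- seq_len(n_seeds)
  for (k in seq_len(n_seeds)) member_a[target_idx[[k]]] <- k

  member_b <- member_a
  for (j in seq_along(diverged)) {
    k <- diverged[j]
    member_b[target_idx[[k]]] <- 0L       # original targets lose the profile
    member_b[repl_idx[[j]]] <- k          # unrelated genes gain it
  }

  draw <- function(member_of, ids) {
    lib <- rlibsize(n_s, config$library_size_cv)
    mu <- module_mu(member_of) %*% diag(lib)
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / config$nb_dispersion),
                     nrow = n_g, dimnames = list(ids, samples$sample_id))
    section_series(counts, samples[, c("sample_id", "tree", "position")],
                   "counts")
  }
  mat_a <- draw(member_a, ids_a)
  mat_b <- draw(member_b, ids_b)

  keep <- rep(TRUE, n_g)
  if (missing_ortholog_fraction > 0) {
    droppable <- setdiff(background, unlist(repl_idx))
    n_drop <- round(missing_ortholog_fraction * n_g)
    keep[sample(droppable, min(n_drop, length(droppable)))] <- FALSE
  }
  orthologs <- data.frame(gene_a = ids_a[keep], gene_b = ids_b[keep],
                          family_id = sprintf("FAM%04d", idx[keep]),
                          stringsAsFactors = FALSE)

  module_edges <- do.call(rbind, lapply(seq_len(n_seeds), function(k) {
    members <- ids_a[c(seed_idx[k], target_idx[[k]])]
    pairs <- utils::combn(sort(members), 2)
    data.frame(gene1 = pairs[1, ], gene2 = pairs[2, ], seed = ids_a[seed_idx[k]],
               stringsAsFactors = FALSE)
  }))

  truth <- list(
    seeds = data.frame(seed_a = ids_a[seed_idx], seed_b = ids_b[seed_idx],
                       diverged = seq_len(n_seeds) %in% diverged,
                       stringsAsFactors = FALSE),
    targets_a = stats::setNames(lapply(target_idx, function(i) ids_a[i]),
                                ids_a[seed_idx]),
    targets_b = stats::setNames(lapply(seq_len(n_seeds), function(k) {
      j <- match(k, diverged)
      if (!is.na(j)) ids_b[repl_idx[[j]]] else ids_b[target_idx[[k]]]
    }), ids_a[seed_idx]),
    module_edges = module_edges,
    orthologs = orthologs)
  list(matrix_a = mat_a, matrix_b = mat_b, truth = truth)
}
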