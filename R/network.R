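#' Pairwise mutual information between gene profiles
#'
#' Estimates MI (in nats) for every gene pair from a discretised joint
#' distribution, `MI = sum p(a,b) log[p(a,b) / (p(a) p(b))]`. Three
#' discretisation schemes are available:
#'
#' * `equal_frequency` (default): rank-based bins of near-equal occupancy,
#'   which makes the estimate invariant under strictly monotone transforms of
#'   either profile and robust to outliers. Ties are broken by sample order.
#' * `equal_width`: bins of equal width over each profile's range.
#' * `bspline`: order-3 B-spline weighted binning, where each sample
#'   contributes fractional mass to up to three adjacent bins (the smoothed
#'   histogram estimator commonly used for expression data).
#'
#' Constant profiles carry no information; their MI against every partner is
#' defined as 0 and the genes are flagged in `attr(, "constant_genes")`.
#'
#' @param x A `section_series` (any value kind; typically vst).
#' @param bins Number of bins `B >= 2`; default `ceiling(sqrt(n_samples))`.
#' @param scheme Discretisation scheme (see above).
#' @return A symmetric gene x gene matrix of class `mi_matrix`, diagonal `NA`,
#'   with attributes `bins`, `scheme` and `constant_genes`.
#' @export
mutual_information <- function(x, bins = NULL,
                               scheme = c("equal_frequency", "equal_width",
                                          "bspline")) {
  stopifnot(inherits(x, "section_series"))
  scheme <- match.arg(scheme)
  v <- x$values
  n <- ncol(v)
  if (n < 8) stop("mutual information requires at least 8 samples")
  if (any(!is.finite(v))) stop("profiles must be finite")
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  if (bins < 2) stop("'bins' must be at least 2")
  if (bins > n) stop("'bins' must not exceed the number of samples")
  g <- nrow(v)
  const <- apply(v, 1, function(r) max(r) == min(r))

  # W[[a]][i, s]: weight of sample s of gene i in bin a (0/1 for hard schemes)
  W <- vector("list", bins)
  if (scheme == "equal_frequency") {
    bin_idx <- t(apply(v, 1, function(r) {
      ceiling(rank(r, ties.method = "first") * bins / n)
    }))
  } else if (scheme == "equal_width") {
    bin_idx <- t(apply(v, 1, function(r) {
      if (max(r) == min(r)) return(rep(1L, n))
      pmin(bins, floor((r - min(r)) / (max(r) - min(r)) * bins) + 1L)
    }))
  }
  if (scheme != "bspline") {
    for (a in seq_len(bins)) W[[a]] <- (bin_idx == a) * 1
  } else {
    ord <- 3L
    if (bins < ord) stop("'bins' must be at least 3 for the bspline scheme")
    knots <- c(rep(0, ord), seq_len(bins - ord) / (bins - ord + 1), rep(1, ord))
    basis_of <- function(r) {
      if (max(r) == min(r)) z <- rep(0.5, n)
      else z <- (r - min(r)) / (max(r) - min(r))
      splines::splineDesign(knots, z, ord = ord, outer.ok = TRUE)
    }
    Wg <- lapply(seq_len(g), function(i) basis_of(v[i, ]))
    for (a in seq_len(bins)) {
      W[[a]] <- t(vapply(Wg, function(m) m[, a], numeric(n)))
    }
  }

  marg <- vapply(W, rowSums, numeric(g))       # g x bins, counts per bin
  logm <- log(marg)
  logm[!is.finite(logm)] <- 0                  # empty bins contribute nothing
  mi <- matrix(0, g, g)
  logn <- log(n)
  for (a in seq_len(bins)) {
    ta <- t(W[[a]])
    for (b in seq_len(bins)) {
      N <- W[[b]] %*% ta                       # N[j, i] = joint count (a_i, b_j)
      contrib <- N * (log(N) + logn)
      contrib[N <= 0] <- 0
      contrib <- contrib - N * outer(logm[, b], logm[, a], "+")
      mi <- mi + t(contrib)
    }
  }
  mi <- mi / n
  mi <- (mi + t(mi)) / 2                        # enforce exact symmetry
  mi[mi < 0] <- 0
  if (any(const)) {
    mi[const, ] <- 0
    mi[, const] <- 0
  }
  diag(mi) <- NA_real_
  dimnames(mi) <- list(gene_ids(x), gene_ids(x))
  structure(mi, class = c("mi_matrix", "matrix"),
            bins = bins, scheme = scheme,
            constant_genes = gene_ids(x)[const])
}

#' Context-likelihood-of-relatedness (CLR) background correction
#'
#' Converts an MI matrix into background-corrected Z-scores: for each gene `i`
#' the null is the empirical distribution of its MI to all other genes, with
#' mean `mu_i` and population SD `sigma_i`; the rectified score is
#' `z_i(j) = max(0, (MI(i,j) - mu_i) / sigma_i)` (0 when `sigma_i = 0`) and
#' the symmetric CLR score is `sqrt(z_i(j)^2 + z_j(i)^2)`.
#'
#' @param mi A symmetric `mi_matrix` over at least 3 genes.
#' @return A symmetric non-negative matrix of class `clr_matrix`, zero
#'   diagonal.
#' @export
clr_transform <- function(mi) {
  m <- unclass(mi)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("'mi' must be a square matrix")
  g <- nrow(m)
  if (g < 3) stop("CLR background is undefined for fewer than 3 genes")
  diag(m) <- 0
  mu <- rowSums(m) / (g - 1)
  d <- m - mu                      # row-wise deviations from the background mean
  diag(d) <- 0                     # diagonal excluded from the background
  sigma <- sqrt(rowSums(d^2) / (g - 1))
  z <- m
  pos <- sigma > 0
  z[pos, ] <- (m[pos, , drop = FALSE] - mu[pos]) / sigma[pos]
  z[!pos, ] <- 0
  z[z < 0] <- 0
  diag(z) <- 0
  clr <- sqrt(z^2 + t(z)^2)
  dimnames(clr) <- dimnames(mi)
  structure(clr, class = c("clr_matrix", "matrix"))
}

# log-binned power-law fit to a degree sequence; returns gamma and R^2
fit_degree_powerlaw <- function(deg) {
  deg <- deg[deg > 0]
  if (!length(deg)) return(list(gamma = NA_real_, r_squared = NA_real_))
  kmax <- max(deg)
  breaks <- 2^(0:max(1, ceiling(log2(kmax + 1))))
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  counts <- vapply(seq_along(lo), function(i) {
    sum(deg >= lo[i] & deg < hi[i])
  }, numeric(1))
  keep <- counts >= 1
  # fewer than 3 occupied bins cannot distinguish a power law from anything
  if (sum(keep) < 3) return(list(gamma = NA_real_, r_squared = NA_real_))
  centers <- sqrt(lo * hi)[keep]
  dens <- counts[keep] / (length(deg) * (hi - lo)[keep])
  fit <- stats::lm(log(dens) ~ log(centers))
  list(gamma = -unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}

#' Scale-freeness-based CLR threshold selection
#'
#' Scans candidate CLR thresholds and, for each, measures how well the degree
#' distribution of the thresholded graph (isolated nodes excluded) follows a
#' power law: degrees are binned logarithmically and `ln P(k) = a - gamma ln k`
#' is fitted by least squares over occupied bins, recording the fit R-squared.
#' The candidate with the highest R-squared among admissible fits wins; ties
#' go to the smallest threshold. A candidate is admissible only if it yields
#' at least `min_edges` edges, at least 3 occupied degree bins, and a decaying
#' fit (`gamma > 0`) -- a dense noise graph whose degrees collapse into one or
#' two bins can produce a spuriously perfect but meaningless line.
#'
#' @param clr A `clr_matrix`.
#' @param candidates Ascending numeric vector of at least 2 candidate
#'   thresholds (a single candidate is returned unchanged with its report).
#' @param min_edges Minimum edge count for a candidate to enter the fit.
#' @return List with `threshold` (selected value) and `report` (data frame:
#'   `threshold`, `n_edges`, `gamma`, `r_squared` per candidate).
#' @export
select_threshold_scale_free <- function(clr, candidates, min_edges = 30) {
  m <- unclass(clr)
  if (!length(candidates)) stop("no candidate thresholds supplied")
  candidates <- sort(unique(as.numeric(candidates)))
  report <- do.call(rbind, lapply(candidates, function(th) {
    adj <- m >= th
    diag(adj) <- FALSE
    deg <- rowSums(adj)
    n_edges <- sum(deg) / 2
    if (n_edges < min_edges) {
      return(data.frame(threshold = th, n_edges = n_edges,
                        gamma = NA_real_, r_squared = NA_real_))
    }
    fit <- fit_degree_powerlaw(deg)
    data.frame(threshold = th, n_edges = n_edges,
               gamma = fit$gamma, r_squared = fit$r_squared)
  }))
  if (length(candidates) == 1) {
    return(list(threshold = candidates, report = report))
  }
  if (all(report$n_edges < min_edges)) {
    stop("all candidate thresholds give fewer than ", min_edges, " edges: ",
         paste(sprintf("%.3g -> %d", report$threshold, report$n_edges),
               collapse = ", "))
  }
  # only decaying degree distributions (gamma > 0) qualify as scale-free
  score <- ifelse(!is.na(report$gamma) & report$gamma > 0,
                  report$r_squared, NA_real_)
  if (all(is.na(score))) {
    stop("no candidate threshold admits a decaying degree-distribution fit")
  }
  best <- which(score == max(score, na.rm = TRUE))[1]
  list(threshold = report$threshold[best], report = report)
}

#' Build the signed co-expression network
#'
#' Links every gene pair whose CLR score is at or above the threshold
#' (inclusive) and annotates each edge with the Pearson correlation of the two
#' variance-stabilised profiles over all samples (trees concatenated in
#' sampling order) and its sign. A correlation of exactly 0 gets sign `"+"`
#' and is flagged via the `zero_r` edge attribute.
#'
#' @param vst A `section_series` providing the profiles.
#' @param clr A `clr_matrix` over the same genes.
#' @param threshold CLR score threshold (edges require `clr >= threshold`).
#' @return An undirected `igraph` with one vertex per gene (isolated vertices
#'   kept), edge attributes `clr_score`, `pearson_r`, `sign`, `zero_r`, and
#'   graph attribute `clr_threshold`.
#' @export
build_network <- function(vst, clr, threshold) {
  stopifnot(inherits(vst, "section_series"))
  m <- unclass(clr)
  genes <- gene_ids(vst)
  only_vst <- setdiff(genes, rownames(m))
  only_clr <- setdiff(rownames(m), genes)
  if (length(only_vst) || length(only_clr)) {
    stop("gene ID mismatch between vst and clr; offending genes: ",
         paste(c(only_vst, only_clr), collapse = ", "))
  }
  m <- m[genes, genes]
  sel <- which(upper.tri(m) & m >= threshold, arr.ind = TRUE)
  if (nrow(sel)) {
    r <- vapply(seq_len(nrow(sel)), function(k) {
      stats::cor(vst$values[sel[k, 1], ], vst$values[sel[k, 2], ])
    }, numeric(1))
    edges <- data.frame(from = genes[sel[, 1]], to = genes[sel[, 2]],
                        clr_score = m[sel],
                        pearson_r = r,
                        sign = ifelse(r < 0, "-", "+"),
                        zero_r = r == 0,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        clr_score = numeric(0), pearson_r = numeric(0),
                        sign = character(0), zero_r = logical(0))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  g <- igraph::set_graph_attr(g, "clr_threshold", threshold)
  g
}

#' Largest connected sub-network
#'
#' Returns the node-induced subgraph of the largest connected component; by
#' construction isolated nodes are never part of it. Size ties are broken
#' towards the component containing the lexicographically smallest gene ID.
#'
#' @param net An `igraph` network from [build_network()].
#' @return The component as an `igraph`.
#' @export
largest_subnetwork <- function(net) {
  if (igraph::ecount(net) == 0) {
    stop("network has no edges; largest sub-network undefined")
  }
  comp <- igraph::components(net)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes[sizes >= 2]))
  if (length(cand) > 1) {
    firsts <- vapply(cand, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1))
    cand <- cand[order(firsts)][1]
  }
  keep <- igraph::V(net)[comp$membership == cand]
  igraph::induced_subgraph(net, keep)
}
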