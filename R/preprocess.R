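#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median, over genes with no
#' zero count, of the ratio between the sample's count and the gene's
#' geometric mean across samples. Rows containing any zero are excluded (the
#' geometric mean is undefined at zero); if no such row exists an error asks
#' for the pseudo-reference fallback, which uses the mean of the log counts
#' over positive entries as the per-gene reference and must be enabled
#' explicitly.
#'
#' @param counts A `section_series` of counts.
#' @param pseudo_reference If `TRUE`, fall back to a log-mean-over-positive
#'   reference when no all-positive gene row exists.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
compute_size_factors <- function(counts, pseudo_reference = FALSE) {
  stopifnot(inherits(counts, "section_series"))
  if (counts$value_kind != "counts") stop("size factors require a counts matrix")
  v <- counts$values
  usable <- rowSums(v <= 0) == 0
  if (!any(usable)) {
    if (!pseudo_reference) {
      stop(paste("no gene has all-positive counts; re-run with",
                 "pseudo_reference = TRUE to use the log-mean over positive",
                 "entries as the per-gene reference"))
    }
    ref <- apply(v, 1, function(r) {
      p <- r[r > 0]
      if (!length(p)) return(NA_real_)
      exp(mean(log(p)))
    })
    keep <- !is.na(ref)
    sf <- apply(v[keep, , drop = FALSE], 2, function(col) {
      ratio <- col / ref[keep]
      stats::median(ratio[col > 0])
    })
  } else {
    logref <- rowMeans(log(v[usable, , drop = FALSE]))
    sf <- apply(v[usable, , drop = FALSE], 2, function(col) {
      stats::median(exp(log(col) - logref))
    })
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("size factor computation produced non-positive factors")
  }
  sf
}

#' Closed-form negative binomial variance-stabilising transform
#'
#' Transforms counts `n` with per-sample size factor `sf` as
#' `t(n) = (2 / ln 2) * asinh(sqrt(alpha * n / sf))`, the variance stabiliser
#' of a negative binomial with variance `mu + alpha * mu^2`. It is strictly
#' increasing, `t(0) = 0`, and behaves as `log2` for large counts, so an
#' expression filter on the familiar "VST > 3" scale applies. If `dispersion`
#' is not supplied it is estimated by method of moments on normalised counts:
#' the median over genes of `max(0, (s^2 - m) / m^2)`, floored at
#' `dispersion_floor`.
#'
#' @param counts A `section_series` of counts.
#' @param size_factors Positive per-sample factors; defaults to
#'   [compute_size_factors()].
#' @param dispersion Optional known dispersion `alpha > 0`.
#' @param dispersion_floor Lower bound for the estimated dispersion.
#' @return A `section_series` with `value_kind = "vst"`; the dispersion used
#'   is stored in `attr(, "dispersion")`.
#' @export
vst_transform <- function(counts, size_factors = compute_size_factors(counts),
                          dispersion = NULL, dispersion_floor = 1e-8) {
  stopifnot(inherits(counts, "section_series"))
  if (counts$value_kind != "counts") stop("vst_transform expects counts")
  if (length(size_factors) != ncol(counts$values) || any(size_factors <= 0) ||
      any(!is.finite(size_factors))) {
    stop("'size_factors' must be positive, one per sample")
  }
  norm <- sweep(counts$values, 2, size_factors, "/")
  if (is.null(dispersion)) {
    m <- rowMeans(norm)
    s2 <- apply(norm, 1, stats::var)
    ok <- m > 0
    est <- pmax(0, (s2[ok] - m[ok]) / m[ok]^2)
    dispersion <- stats::median(est)
    if (!is.finite(dispersion) || dispersion <= 0) {
      warning("dispersion estimate not positive; using the floor")
      dispersion <- dispersion_floor
    }
    dispersion <- max(dispersion, dispersion_floor)
  } else if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("'dispersion' must be a positive real")
  }
  t_vals <- (2 / log(2)) * asinh(sqrt(dispersion * norm))
  out <- section_series(t_vals, counts$sample_meta, "vst")
  attr(out, "dispersion") <- dispersion
  attr(out, "size_factors") <- size_factors
  out
}

#' Expression filter across replicate trees
#'
#' Keeps a gene when, in at least `min_trees` replicate trees, its
#' variance-stabilised expression strictly exceeds `vst_threshold` in at least
#' `min_samples_per_tree` samples of that tree. The inequality is strict: a
#' value exactly at the threshold does not count.
#'
#' @param vst A `section_series` with `value_kind = "vst"`.
#' @param vst_threshold Expression threshold (strict `>`).
#' @param min_samples_per_tree Samples per tree that must exceed the threshold.
#' @param min_trees Number of trees in which the per-tree condition must hold.
#' @return Character vector of kept gene IDs, in input order.
#' @export
filter_expressed <- function(vst, vst_threshold = 3, min_samples_per_tree = 2,
                             min_trees = 2) {
  stopifnot(inherits(vst, "section_series"))
  if (vst$value_kind != "vst") stop("filter_expressed expects a vst matrix")
  if (vst_threshold <= 0 || min_samples_per_tree < 1 || min_trees < 1) {
    stop("thresholds must be positive")
  }
  trees <- unique(vst$sample_meta$tree)
  if (min_trees > length(trees)) {
    stop("'min_trees' exceeds the number of trees")
  }
  per_tree_n <- table(vst$sample_meta$tree)
  if (any(per_tree_n < min_samples_per_tree)) {
    bad <- names(per_tree_n)[per_tree_n < min_samples_per_tree]
    stop("filter undefined: tree(s) with fewer than min_samples_per_tree samples: ",
         paste(bad, collapse = ", "))
  }
  hits <- sapply(trees, function(tr) {
    cols <- vst$sample_meta$tree == tr
    rowSums(vst$values[, cols, drop = FALSE] > vst_threshold) >=
      min_samples_per_tree
  })
  keep <- rowSums(hits) >= min_trees
  gene_ids(vst)[keep]
}

#' Impute a missing sample from its flanking sections
#'
#' Inserts a column for a sample that failed, as the arithmetic mean of the
#' two samples immediately before and after it within the same tree. There is
#' no defined rule for a missing sample at either end of a series, so both
#' flanking positions must be present.
#'
#' @param x A `section_series` (counts or vst; an imputed count column may be
#'   fractional, which downstream normalisation handles unchanged).
#' @param tree Tree identifier of the missing sample.
#' @param position Integer position of the missing sample within that tree.
#' @return A `section_series` with the imputed column inserted in position
#'   order; all other columns are unchanged.
#' @export
impute_missing_sample <- function(x, tree, position) {
  stopifnot(inherits(x, "section_series"))
  meta <- x$sample_meta
  if (any(meta$tree == tree & meta$position == position)) {
    stop(sprintf("sample at tree '%s' position %d already present", tree, position))
  }
  before <- which(meta$tree == tree & meta$position == position - 1)
  after <- which(meta$tree == tree & meta$position == position + 1)
  if (length(before) != 1 || length(after) != 1) {
    stop(sprintf(paste("cannot impute tree '%s' position %d: both flanking",
                       "positions must exist (no rule for a series end)"),
         tree, position))
  }
  if (after != before + 1) {
    stop("flanking samples are not adjacent columns; reorder the matrix by tree and position")
  }
  newcol <- (x$values[, before] + x$values[, after]) / 2
  new_id <- sprintf("%s:%02d", tree, position)
  if (new_id %in% meta$sample_id) new_id <- sprintf("%s:%02d.imputed", tree, position)
  vals <- cbind(x$values[, seq_len(before), drop = FALSE],
                newcol,
                x$values[, seq(after, ncol(x$values)), drop = FALSE])
  colnames(vals)[before + 1] <- new_id
  meta2 <- rbind(meta[seq_len(before), , drop = FALSE],
                 data.frame(sample_id = new_id, tree = tree,
                            position = as.integer(position),
                            stringsAsFactors = FALSE),
                 meta[seq(after, nrow(meta)), , drop = FALSE])
  rownames(meta2) <- NULL
  section_series(vals, meta2, x$value_kind)
}
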