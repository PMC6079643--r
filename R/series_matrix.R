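#' Section-series expression matrix
#'
#' The central data container of the package: a gene x sample value matrix
#' from a tangential cryosection series, together with per-sample metadata
#' recording which replicate tree each sample came from and its position along
#' the developmental axis (phloem side towards latewood). Values are either
#' raw counts or variance-stabilised expression.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must carry
#'   unique, non-empty rownames (gene IDs) and colnames (sample IDs).
#' @param sample_meta Data frame with columns `sample_id`, `tree`, `position`;
#'   one row per column of `values`, in column order. Positions are integers
#'   `>= 1` and must be strictly increasing within each tree.
#' @param value_kind Either `"counts"` (non-negative; fractional values are
#'   allowed so that rescaled or estimated counts remain representable) or
#'   `"vst"`.
#' @return An object of class `section_series`.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'   dimnames = list(paste0("G", 1:3), c("T1:01", "T1:02", "T2:01", "T2:02")))
#' meta <- data.frame(sample_id = colnames(m),
#'   tree = rep(c("T1", "T2"), each = 2), position = rep(1:2, 2))
#' section_series(m, meta, "counts")
#' @export
section_series <- function(values, sample_meta, value_kind = c("counts", "vst")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyDuplicated(gid) || any(!nzchar(gid))) {
    stop("'values' must have unique, non-empty rownames (gene IDs)")
  }
  if (is.null(sid) || anyDuplicated(sid) || any(!nzchar(sid))) {
    stop("'values' must have unique, non-empty colnames (sample IDs)")
  }
  if (!is.data.frame(sample_meta) ||
      !all(c("sample_id", "tree", "position") %in% names(sample_meta))) {
    stop("'sample_meta' must be a data.frame with sample_id, tree, position")
  }
  if (nrow(sample_meta) != ncol(values) ||
      !identical(as.character(sample_meta$sample_id), sid)) {
    stop("'sample_meta$sample_id' must match colnames(values) in order")
  }
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (value_kind == "counts" && any(values < 0)) {
    stop("count values must be non-negative")
  }
  pos <- as.integer(sample_meta$position)
  if (any(is.na(pos)) || any(pos < 1)) {
    stop("'position' must be integers >= 1")
  }
  for (tr in unique(sample_meta$tree)) {
    p <- pos[sample_meta$tree == tr]
    if (any(diff(p) <= 0)) {
      stop(sprintf("positions must be strictly increasing within tree '%s'", tr))
    }
  }
  meta <- data.frame(sample_id = sid,
                     tree = as.character(sample_meta$tree),
                     position = pos,
                     stringsAsFactors = FALSE)
  structure(list(values = values, sample_meta = meta, value_kind = value_kind),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("section_series: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  tab <- table(x$sample_meta$tree)
  cat("  trees:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Gene and sample identifiers
#' @param x A `section_series` object.
#' @return Character vector of IDs.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset a section series by genes and/or samples
#'
#' @param x A `section_series`.
#' @param genes,samples Character vectors of IDs to keep (order preserved);
#'   `NULL` keeps all.
#' @return A `section_series` restricted to the requested rows/columns.
#' @export
subset_series <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "section_series"))
  if (is.null(genes)) genes <- gene_ids(x)
  if (is.null(samples)) samples <- sample_ids(x)
  missing_g <- setdiff(genes, gene_ids(x))
  if (length(missing_g)) {
    stop("unknown genes: ", paste(missing_g, collapse = ", "))
  }
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_s)) {
    stop("unknown samples: ", paste(missing_s, collapse = ", "))
  }
  v <- x$values[genes, samples, drop = FALSE]
  meta <- x$sample_meta[match(samples, x$sample_meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  section_series(v, meta, x$value_kind)
}

#' Remove one sample from a series
#'
#' Convenience used to exercise the missing-sample imputation rule: drops the
#' column at a given tree/position.
#'
#' @param x A `section_series`.
#' @param tree Tree identifier.
#' @param position Integer position within that tree.
#' @return The series without that sample.
#' @export
drop_sample <- function(x, tree, position) {
  stopifnot(inherits(x, "section_series"))
  hit <- x$sample_meta$tree == tree & x$sample_meta$position == position
  if (!any(hit)) {
    stop(sprintf("no sample at tree '%s' position %d", tree, position))
  }
  keep <- sample_ids(x)[!hit]
  subset_series(x, samples = keep)
}
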