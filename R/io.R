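#' Read an expression TSV
#'
#' The dialect is a UTF-8 TSV whose header row is `gene_id` followed by sample
#' IDs encoding tree and position as `tree:position` (e.g. `T1:03`); the body
#' is numeric. Duplicate gene or sample IDs, ragged rows and non-numeric cells
#' are rejected with the offending line.
#'
#' @param path File path.
#' @param value_kind `"counts"` or `"vst"`.
#' @return A `section_series`.
#' @export
read_expression_tsv <- function(path, value_kind = c("counts", "vst")) {
  value_kind <- match.arg(value_kind)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "gene_id") {
    stop("line 1: header must start with 'gene_id' followed by sample IDs")
  }
  sids <- header[-1]
  if (anyDuplicated(sids)) stop("line 1: duplicate sample IDs in header")
  parts <- strsplit(sids, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("line 1: sample IDs must have the form tree:position")
  }
  tree <- vapply(parts, `[`, character(1), 1)
  pos <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  if (any(is.na(pos))) stop("line 1: sample positions must be integers")
  body <- lines[-1]
  body <- body[nzchar(body)]          # tolerate trailing blank lines
  if (!length(body)) stop("file has a header but no data rows")
  cells <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad)) {
    stop(sprintf("line %d: expected %d fields, found %d",
                 bad[1] + 1, length(header), length(cells[[bad[1]]])))
  }
  gids <- vapply(cells, `[`, character(1), 1)
  if (anyDuplicated(gids)) stop("duplicate gene IDs in column 1")
  vals <- suppressWarnings(
    t(vapply(cells, function(r) as.numeric(r[-1]), numeric(length(sids)))))
  nas <- which(rowSums(is.na(vals)) > 0)
  if (length(nas)) stop(sprintf("line %d: non-numeric cell", nas[1] + 1))
  dimnames(vals) <- list(gids, sids)
  meta <- data.frame(sample_id = sids, tree = tree, position = pos,
                     stringsAsFactors = FALSE)
  section_series(vals, meta, value_kind)
}

#' Write an expression TSV
#'
#' @param x A `section_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "section_series"))
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One term per line: `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @param universe Gene universe for the collection; defaults to the union of
#'   all set members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop(sprintf("line %d: GMT lines need term, description and >= 1 gene",
                 short[1]))
  }
  terms <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(terms)) stop("duplicate term IDs in GMT")
  desc <- stats::setNames(vapply(fields, `[`, character(1), 2), terms)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), terms)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, desc)
}

#' Write gene sets in GMT format
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(term) {
    paste(c(term, collection$descriptions[term], collection$sets[[term]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an ortholog map TSV
#'
#' Columns `gene_a`, `gene_b` and optionally `family_id`; duplicate pairs and
#' empty IDs are rejected.
#'
#' @param path File path.
#' @return Data frame of ortholog pairs.
#' @export
read_orthologs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    stop("ortholog TSV needs columns gene_a and gene_b")
  }
  if (any(!nzchar(df$gene_a)) || any(!nzchar(df$gene_b))) {
    stop("ortholog TSV contains empty gene IDs")
  }
  if (anyDuplicated(df[, c("gene_a", "gene_b")])) {
    stop("ortholog TSV contains duplicate pairs")
  }
  df
}

#' Write an ortholog map TSV
#' @param orthologs Data frame with `gene_a`, `gene_b` (and more).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthologs <- function(orthologs, path) {
  utils::write.table(orthologs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a gene annotation TSV (TF flag and planted cluster)
#' @param annotation Data frame with at least `gene_id`, `is_tf`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene annotation TSV
#' @param path File path.
#' @return Data frame with `is_tf` as logical.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "is_tf") %in% names(df))) {
    stop("annotation TSV needs columns gene_id and is_tf")
  }
  df$is_tf <- as.logical(df$is_tf)
  df
}

#' Write a network as an edge-list TSV
#'
#' Columns: `gene1`, `gene2`, `clr_score`, `pearson_r`, `sign`. Scores are
#' written at full precision so the round trip is exact.
#'
#' @param net An `igraph` from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  df <- data.frame(gene1 = el$from, gene2 = el$to,
                   clr_score = sprintf("%.17g", el$clr_score),
                   pearson_r = sprintf("%.17g", el$pearson_r),
                   sign = el$sign, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a network edge-list TSV
#'
#' @param path File path.
#' @param vertices Optional character vector of all gene IDs (to preserve
#'   isolated nodes).
#' @param threshold Optional build threshold to record on the graph.
#' @return An `igraph`.
#' @export
read_network <- function(path, vertices = NULL, threshold = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene1 = "character",
                                         gene2 = "character",
                                         clr_score = "numeric",
                                         pearson_r = "numeric",
                                         sign = "character"))
  edges <- data.frame(from = df$gene1, to = df$gene2,
                      clr_score = df$clr_score, pearson_r = df$pearson_r,
                      sign = df$sign, zero_r = df$pearson_r == 0,
                      stringsAsFactors = FALSE)
  vv <- if (is.null(vertices)) unique(c(df$gene1, df$gene2)) else vertices
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = vv))
  if (!is.null(threshold)) {
    g <- igraph::set_graph_attr(g, "clr_threshold", threshold)
  }
  g
}

#' Export a network to GraphML
#'
#' Edges carry `clr_score`, `pearson_r` and `sign`; if a centrality table is
#' supplied its columns are attached as vertex attributes so network viewers
#' can style by them.
#'
#' @param net An `igraph` from [build_network()].
#' @param path Output path.
#' @param centrality_table Optional data frame from [centralities()].
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, centrality_table = NULL) {
  if (!is.null(centrality_table)) {
    idx <- match(igraph::V(net)$name, centrality_table$gene)
    for (col in setdiff(names(centrality_table), "gene")) {
      net <- igraph::set_vertex_attr(net, col, value = centrality_table[[col]][idx])
    }
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a conservation report as TSV and JSON
#'
#' The hypergeometric conservation statistic is this package's own
#' quantification of a qualitative presence/absence readout; the JSON carries
#' a `statistic` field saying so.
#'
#' @param report Data frame from [conservation_report()].
#' @param path Output path without extension; `.tsv` and `.json` are written.
#' @return The two paths, invisibly.
#' @export
write_report <- function(report, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  jsonlite::write_json(list(
    statistic = "hypergeometric neighbourhood overlap (package-defined quantification)",
    rows = report), json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, json))
}
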