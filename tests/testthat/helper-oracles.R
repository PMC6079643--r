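# Brute-force reference implementations, independent of the package's code
# paths, plus small fixture builders.

# quick section_series from a bare matrix; samples split evenly over trees
mk_series <- function(X, n_trees = 1, value_kind = "vst") {
  n <- ncol(X)
  rn <- rownames(X)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn))) {
    rownames(X) <- sprintf("G%03d", seq_len(nrow(X)))
  }
  tree <- paste0("T", rep(seq_len(n_trees), each = ceiling(n / n_trees),
                          length.out = n))
  pos <- as.integer(stats::ave(seq_len(n), tree, FUN = seq_along))
  ids <- sprintf("%s:%02d", tree, pos)
  colnames(X) <- ids
  section_series(X, data.frame(sample_id = ids, tree = tree, position = pos),
                 value_kind)
}

# CLR by definition, scalar loops only
clr_oracle <- function(mi) {
  m <- unclass(mi)
  diag(m) <- 0
  g <- nrow(m)
  z <- matrix(0, g, g)
  for (i in seq_len(g)) {
    bg <- m[i, -i]
    mu <- mean(bg)
    sg <- sqrt(mean((bg - mu)^2))
    for (j in seq_len(g)) {
      if (j == i) next
      z[i, j] <- if (sg > 0) max(0, (m[i, j] - mu) / sg) else 0
    }
  }
  out <- matrix(0, g, g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    out[i, j] <- sqrt(z[i, j]^2 + z[j, i]^2)
  }
  dimnames(out) <- dimnames(mi)
  out
}

# all-pairs BFS + explicit shortest-path counting (Brandes accumulation),
# written against an adjacency list, not igraph
centrality_oracle <- function(adj) {
  # adj: 0/1 symmetric matrix
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1))
  btw <- numeric(n)
  far <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    far[s] <- sum(dist[dist > 0])
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) btw[w] <- btw[w] + delta[w]
    }
  }
  deg <- rowSums(adj)
  annd <- vapply(seq_len(n), function(i) {
    if (deg[i] == 0) return(NaN)
    mean(deg[nbrs[[i]]])
  }, numeric(1))
  list(degree = deg, betweenness = btw / 2, farness = far,
       avg_neighbor_degree = annd)
}

# component labelling by plain BFS
components_oracle <- function(adj) {
  n <- nrow(adj)
  label <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (label[s] > 0) next
    cur <- cur + 1L
    queue <- s; label[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] == 1)) {
        if (label[w] == 0) { label[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  label
}

# hypergeometric upper tail as an explicit sum of point masses
hyper_tail_oracle <- function(overlap, term_size, universe, query_size) {
  ks <- overlap:min(term_size, query_size)
  sum(stats::dhyper(ks, term_size, universe - term_size, query_size))
}

# undirected edge key helper for set comparisons
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
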