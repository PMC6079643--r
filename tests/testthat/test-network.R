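test_that("MI of a duplicated tie-free profile equals ln(B) under equal-frequency bins", {
  set.seed(1)
  x <- stats::rnorm(50)
  s <- mk_series(rbind(x, x))
  for (B in c(2, 5, 10)) {
    mi <- mutual_information(s, bins = B)
    expect_equal(mi[1, 2], log(B), tolerance = 1e-12)
  }
})

test_that("MI of independent profiles stays near zero", {
  set.seed(7)
  s <- mk_series(rbind(stats::rnorm(1000), stats::rnorm(1000)))
  mi <- mutual_information(s, bins = 10)
  expect_lte(mi[1, 2], 0.1)   # bias is about (B-1)^2 / (2n) = 0.04
})

test_that("MI recovers the Gaussian closed form for a correlated pair", {
  set.seed(42)
  n <- 5000; rho <- 0.9
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  mi <- mutual_information(mk_series(rbind(x, y)), bins = ceiling(n^(1 / 3)))
  expect_lt(abs(mi[1, 2] - (-0.5 * log(1 - rho^2))), 0.12)
})

test_that("equal-frequency MI is symmetric and monotone-transform invariant", {
  set.seed(5)
  X <- matrix(stats::rnorm(5 * 40), 5, 40)
  s <- mk_series(X)
  mi <- mutual_information(s, bins = 6)
  expect_equal(unclass(mi), t(unclass(mi)))
  # strictly monotone transform of one profile leaves rank bins unchanged
  X2 <- X
  X2[2, ] <- exp(3 * X2[2, ]) + 1
  mi2 <- mutual_information(mk_series(X2), bins = 6)
  expect_equal(unclass(mi), unclass(mi2), tolerance = 1e-12)
})

test_that("constant profiles are flagged and carry zero MI", {
  X <- rbind(rep(2, 20), stats::rnorm(20), stats::rnorm(20))
  mi <- mutual_information(mk_series(X), bins = 4)
  expect_identical(attr(mi, "constant_genes"), "G001")
  expect_equal(mi[1, 2], 0)
  expect_equal(mi[1, 3], 0)
})

test_that("MI input contracts are enforced", {
  X <- matrix(stats::rnorm(2 * 10), 2, 10)
  expect_error(mutual_information(mk_series(X), bins = 11), "bins")
  expect_error(mutual_information(mk_series(X), bins = 1), "bins")
  expect_error(mutual_information(mk_series(X[, 1:6, drop = FALSE])), "8 samples")
})

test_that("the B-spline estimator detects dependence above its null", {
  set.seed(9)
  n <- 200
  x <- stats::rnorm(n)
  y <- 0.95 * x + sqrt(1 - 0.95^2) * stats::rnorm(n)
  z <- stats::rnorm(n)
  mi <- mutual_information(mk_series(rbind(x, y, z)), bins = 7,
                           scheme = "bspline")
  expect_gt(mi[1, 2], 5 * max(mi[1, 3], mi[2, 3]))
  expect_equal(unclass(mi), t(unclass(mi)))
})

test_that("CLR matches the worked 3-gene example", {
  M <- matrix(c(NA, 0.2, 0.5, 0.2, NA, 0.8, 0.5, 0.8, NA), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  cc <- clr_transform(M)
  # gene 1 background {0.2, 0.5}: z1(3) = +1; gene 3 background {0.5, 0.8}:
  # z3(1) = -1, rectified to 0 -> CLR(1,3) = 1
  expect_equal(cc["g1", "g3"], 1, tolerance = 1e-12)
  expect_equal(diag(cc), stats::setNames(rep(0, 3), paste0("g", 1:3)))
})

test_that("a flat MI background collapses CLR to zero", {
  M <- matrix(0.4, 4, 4); diag(M) <- NA
  dimnames(M) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_true(all(clr_transform(M) == 0))
})

test_that("CLR equals the brute-force oracle on random matrices", {
  set.seed(13)
  for (rep in 1:100) {
    M <- matrix(stats::runif(100), 10, 10)
    M <- (M + t(M)) / 2
    diag(M) <- NA
    dimnames(M) <- list(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10))
    expect_equal(unclass(clr_transform(M)), clr_oracle(M), tolerance = 1e-12)
  }
})

test_that("CLR is invariant to a constant shift of all off-diagonal MI", {
  set.seed(3)
  M <- matrix(stats::runif(64), 8, 8); M <- (M + t(M)) / 2; diag(M) <- NA
  dimnames(M) <- list(paste0("g", 1:8), paste0("g", 1:8))
  M2 <- M + 0.7
  expect_equal(unclass(clr_transform(M)), unclass(clr_transform(M2)),
               tolerance = 1e-12)
})

test_that("CLR needs at least three genes", {
  M <- matrix(c(NA, 1, 1, NA), 2, 2)
  expect_error(clr_transform(M), "3 genes")
})

test_that("threshold selection recovers a planted scale-free graph", {
  set.seed(11)
  g <- igraph::sample_pa(200, m = 2, directed = FALSE)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- 200
  clr <- matrix(stats::runif(n * n, 0, 4.8), n, n)
  clr[A == 1] <- stats::runif(sum(A == 1), 5, 5.4)
  clr[lower.tri(clr)] <- t(clr)[lower.tri(clr)]
  diag(clr) <- 0
  dimnames(clr) <- list(sprintf("G%03d", 1:n), sprintf("G%03d", 1:n))
  sel <- select_threshold_scale_free(clr, c(3, 4, 5, 6))
  expect_equal(sel$threshold, 5)
  expect_equal(nrow(sel$report), 4)
  expect_gt(sel$report$r_squared[sel$report$threshold == 5], 0.9)
})

test_that("threshold selection tie-break and degenerate cases", {
  # two thresholds yielding the same graph have bitwise-equal fits -> smaller wins
  set.seed(2)
  g <- igraph::sample_pa(150, m = 2, directed = FALSE)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  clr <- A * 6  # edges at 6, everything else 0
  dimnames(clr) <- list(sprintf("G%03d", 1:150), sprintf("G%03d", 1:150))
  sel <- select_threshold_scale_free(clr, c(2, 3))
  expect_equal(sel$threshold, 2)
  # single candidate returned unchanged
  sel1 <- select_threshold_scale_free(clr, 5)
  expect_equal(sel1$threshold, 5)
  expect_equal(nrow(sel1$report), 1)
  # all candidates below the edge floor -> error listing counts
  expect_error(select_threshold_scale_free(clr, c(7, 8)), "fewer than 30")
})

test_that("network construction annotates signed edges and respects the threshold", {
  x <- stats::rnorm(20)
  X <- rbind(a = x, b = x, c = -x, d = stats::rnorm(20))
  s <- mk_series(X); rownames(s$values) <- c("a", "b", "c", "d")
  clr <- matrix(0, 4, 4, dimnames = list(c("a", "b", "c", "d"),
                                         c("a", "b", "c", "d")))
  clr["a", "b"] <- clr["b", "a"] <- 6
  clr["a", "c"] <- clr["c", "a"] <- 5    # inclusive boundary
  clr["a", "d"] <- clr["d", "a"] <- 4.9  # below threshold
  net <- build_network(s, clr, 5)
  expect_equal(igraph::ecount(net), 2)
  eattr <- igraph::as_data_frame(net, what = "edges")
  ab <- eattr[edge_key(eattr$from, eattr$to) == edge_key("a", "b"), ]
  ac <- eattr[edge_key(eattr$from, eattr$to) == edge_key("a", "c"), ]
  expect_equal(ab$pearson_r, 1)
  expect_equal(ab$sign, "+")
  expect_equal(ac$pearson_r, -1)
  expect_equal(ac$sign, "-")
  # above max CLR -> empty edge set but all nodes kept
  net0 <- build_network(s, clr, 100)
  expect_equal(igraph::ecount(net0), 0)
  expect_equal(igraph::vcount(net0), 4)
  # mismatched gene sets are named
  clr_bad <- clr[1:3, 1:3]
  expect_error(build_network(s, clr_bad, 5), "d")
})

test_that("the edge set is monotone decreasing in the threshold", {
  set.seed(21)
  M <- matrix(stats::runif(225, 0, 8), 15, 15); M <- (M + t(M)) / 2; diag(M) <- 0
  ids <- sprintf("G%03d", 1:15)
  dimnames(M) <- list(ids, ids)
  X <- matrix(stats::rnorm(15 * 12), 15, 12, dimnames = list(ids, NULL))
  s <- mk_series(X); rownames(s$values) <- ids
  prev <- NULL
  for (th in c(2, 4, 6)) {
    net <- build_network(s, M, th)
    el <- igraph::as_data_frame(net, what = "edges")
    keys <- edge_key(el$from, el$to)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("largest sub-network matches BFS component labelling", {
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    A <- matrix(stats::rbinom(n * n, 1, 0.06), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    ids <- sprintf("G%03d", seq_len(n))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    igraph::V(g)$name <- ids
    if (igraph::ecount(g) == 0) next
    lab <- components_oracle(A)
    comp_sizes <- table(lab)
    big <- names(comp_sizes)[comp_sizes == max(comp_sizes)]
    # oracle tie-break: smallest gene ID among max-size components
    firsts <- vapply(big, function(ci) min(ids[lab == as.integer(ci)]),
                     character(1))
    want <- sort(ids[lab == as.integer(big[order(firsts)][1])])
    sub <- largest_subnetwork(g)
    expect_equal(sort(igraph::V(sub)$name), want)
  }
  # a connected network is returned whole
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  expect_equal(igraph::vcount(largest_subnetwork(ring)), 6)
  # edgeless network errors
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- letters[1:3]
  expect_error(largest_subnetwork(empty), "no edges")
})
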