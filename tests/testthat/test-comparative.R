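# toy weighted network helper: edges as data.frame(from, to, clr_score)
mk_net <- function(edges, vertices, threshold = 0) {
  edges$pearson_r <- 1
  edges$sign <- "+"
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = vertices))
  igraph::set_graph_attr(g, "clr_threshold", threshold)
}

test_that("neighbourhood extraction honours the inclusive threshold", {
  edges <- data.frame(from = rep("s", 4), to = paste0("n", 1:4),
                      clr_score = c(5, 5, 6, 4.9))
  net <- mk_net(edges, c("s", paste0("n", 1:4), "iso"))
  nb <- neighborhood(net, "s", threshold = 5)
  expect_setequal(igraph::V(nb)$name, c("s", "n1", "n2", "n3"))
  # seed with no qualifying edges is its own neighbourhood
  nb9 <- neighborhood(net, "s", threshold = 9)
  expect_equal(igraph::V(nb9)$name, "s")
  expect_equal(igraph::ecount(nb9), 0)
  # absent seeds: warning when some, error when all
  expect_warning(nb2 <- neighborhood(net, c("s", "ghost"), threshold = 5),
                 "ghost")
  expect_equal(igraph::graph_attr(nb2, "absent_seeds"), "ghost")
  expect_error(suppressWarnings(neighborhood(net, "ghost")), "none")
  # re-filtering below the build threshold is refused
  net5 <- mk_net(edges, c("s", paste0("n", 1:4)), threshold = 5)
  expect_error(neighborhood(net5, "s", threshold = 3), "upward")
})

test_that("multi-seed neighbourhoods equal the union of per-seed neighbourhoods", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 25
    A <- matrix(stats::rbinom(n * n, 1, 0.12), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    idx <- which(A == 1, arr.ind = TRUE)
    ids <- sprintf("g%02d", 1:n)
    edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                        clr_score = stats::runif(nrow(idx), 3, 8))
    net <- mk_net(edges, ids)
    seeds <- sample(ids, 3)
    th <- 5
    joint <- igraph::V(neighborhood(net, seeds, threshold = th))$name
    single <- unique(unlist(lapply(seeds, function(s) {
      igraph::V(neighborhood(net, s, threshold = th))$name
    })))
    expect_setequal(joint, single)
  }
})

test_that("expansion is monotone, one step at a time, fixed on cliques", {
  # path graph: expansion from one end adds exactly one node per call
  ids <- paste0("p", 1:5)
  edges <- data.frame(from = ids[1:4], to = ids[2:5], clr_score = 6)
  net <- mk_net(edges, ids)
  cur <- "p1"
  for (i in 2:5) {
    cur <- expand_neighborhood(net, cur, threshold = 5)
    expect_setequal(cur, ids[1:i])
  }
  # clique is a fixed point
  cl <- igraph::make_full_graph(4)
  igraph::V(cl)$name <- paste0("c", 1:4)
  igraph::E(cl)$clr_score <- 6
  cl <- igraph::set_graph_attr(cl, "clr_threshold", 0)
  expect_setequal(expand_neighborhood(cl, paste0("c", 1:4), threshold = 5),
                  paste0("c", 1:4))
  expect_error(expand_neighborhood(net, character(0)), "empty")
})

test_that("one neighbourhood step then one expansion equals BFS to depth 2", {
  set.seed(25)
  for (rep in 1:5) {
    n <- 30
    A <- matrix(stats::rbinom(n * n, 1, 0.1), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    idx <- which(A == 1, arr.ind = TRUE)
    ids <- sprintf("g%02d", 1:n)
    edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                        clr_score = stats::runif(nrow(idx), 3, 8))
    net <- mk_net(edges, ids)
    th <- 4.5
    seed <- sample(ids, 1)
    nb1 <- igraph::V(neighborhood(net, seed, threshold = th))$name
    two <- expand_neighborhood(net, nb1, threshold = th)
    # oracle: BFS to depth 2 on the thresholded adjacency
    A2 <- matrix(0, n, n, dimnames = list(ids, ids))
    qual <- edges[edges$clr_score >= th, ]
    for (r in seq_len(nrow(qual))) {
      A2[qual$from[r], qual$to[r]] <- A2[qual$to[r], qual$from[r]] <- 1
    }
    d1 <- ids[A2[seed, ] == 1]
    d2 <- unique(c(seed, d1, ids[colSums(A2[c(seed, d1), , drop = FALSE]) > 0]))
    expect_setequal(two, d2)
  }
})

test_that("TF subsetting preserves order and tolerates empty results", {
  ann <- data.frame(gene_id = c("a", "b", "c", "d"),
                    is_tf = c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(tf_subset(c("d", "c", "a"), ann), c("c", "a"))
  expect_identical(tf_subset(c("b", "d"), ann), character(0))
  expect_identical(tf_subset(c("a", "c"), ann), c("a", "c"))
  expect_error(tf_subset("a", data.frame(gene = "a")), "annotation")
})

test_that("probe membership distinguishes absence from non-neighbourhood", {
  edges <- data.frame(from = c("s", "x"), to = c("a", "y"),
                      clr_score = c(6, 6))
  net <- mk_net(edges, c("s", "a", "x", "y"))
  res <- neighborhood_membership(net, "s", c("a", "y", "ghost", "s"),
                                 threshold = 5)
  expect_equal(res$in_neighborhood[res$probe == "a"], TRUE)
  expect_equal(res$in_neighborhood[res$probe == "y"], FALSE)  # other component
  expect_true(is.na(res$in_neighborhood[res$probe == "ghost"]))
  expect_false(res$in_network[res$probe == "ghost"])
  expect_true(res$is_seed[res$probe == "s"])
  expect_equal(res$in_neighborhood[res$probe == "s"], TRUE)
  expect_error(neighborhood_membership(net, "ghost", "a"), "not in the network")
  # random graphs: membership equals the adjacency oracle
  set.seed(33)
  for (rep in 1:5) {
    n <- 15
    A <- matrix(stats::rbinom(n * n, 1, 0.2), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    idx <- which(A == 1, arr.ind = TRUE)
    if (!nrow(idx)) next
    ids <- sprintf("g%02d", 1:n)
    dimnames(A) <- list(ids, ids)
    edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                        clr_score = 6)
    net <- mk_net(edges, ids)
    A <- A + t(A)
    seed <- ids[which(rowSums(A) > 0)[1]]
    res <- neighborhood_membership(net, seed, ids, threshold = 5)
    want <- A[seed, ] == 1 | ids == seed
    expect_equal(res$in_neighborhood, unname(want))
  }
})

test_that("identical networks under an identity map are fully conserved", {
  edges <- data.frame(from = rep("A_s", 3), to = paste0("A_t", 1:3),
                      clr_score = 6)
  ids_a <- c("A_s", paste0("A_t", 1:3), paste0("A_bg", 1:6))
  net_a <- mk_net(edges, ids_a)
  edges_b <- edges; edges_b$from <- sub("^A_", "B_", edges_b$from)
  edges_b$to <- sub("^A_", "B_", edges_b$to)
  net_b <- mk_net(edges_b, sub("^A_", "B_", ids_a))
  omap <- data.frame(gene_a = ids_a, gene_b = sub("^A_", "B_", ids_a))
  row <- conservation_test(net_a, net_b, omap, "A_s",
                           threshold_a = 5, threshold_b = 5)
  expect_equal(row$overlap_fraction, 1)
  expect_equal(row$verdict, "conserved")
  # direction symmetry
  omap_rev <- data.frame(gene_a = omap$gene_b, gene_b = omap$gene_a)
  row_rev <- conservation_test(net_b, net_a, omap_rev, "B_s",
                               threshold_a = 5, threshold_b = 5)
  expect_equal(row_rev$verdict, row$verdict)
  expect_equal(row_rev$overlap_fraction, row$overlap_fraction)
  # a seed with no ortholog is untestable
  omap2 <- omap[omap$gene_a != "A_s", ]
  row2 <- conservation_test(net_a, net_b, omap2, "A_s",
                            threshold_a = 5, threshold_b = 5)
  expect_equal(row2$verdict, "untestable")
  expect_error(conservation_test(net_a, net_b, omap, "nope"), "network A")
})

test_that("raising the B-side threshold weakly reduces the overlap fraction", {
  set.seed(55)
  ids_a <- c("A_s", paste0("A_t", 1:5))
  edges_a <- data.frame(from = "A_s", to = paste0("A_t", 1:5), clr_score = 7)
  net_a <- mk_net(edges_a, ids_a)
  ids_b <- sub("^A_", "B_", ids_a)
  edges_b <- data.frame(from = "B_s", to = paste0("B_t", 1:5),
                        clr_score = c(4, 5, 6, 7, 8))
  net_b <- mk_net(edges_b, ids_b)
  omap <- data.frame(gene_a = ids_a, gene_b = ids_b)
  prev <- Inf
  for (th in c(4, 5, 6, 7, 8, 9)) {
    row <- conservation_test(net_a, net_b, omap, "A_s",
                             threshold_a = 5, threshold_b = th)
    frac <- if (is.na(row$overlap_fraction)) 0 else row$overlap_fraction
    expect_lte(frac, prev)
    prev <- frac
  }
})

test_that("the planted diverged seed is the one flagged on simulated species", {
  cfg <- simulation_config(n_genes = 300, n_trees = 5,
                           samples_per_tree = rep(18, 5), peak_width = 0.10,
                           amplitude = 600, nb_dispersion = 0.05, rng_seed = 7)
  sp <- simulate_species_pair(cfg, n_seeds = 5, n_targets_per_seed = 8,
                              n_diverged = 1)
  prep <- function(m) {
    v <- vst_transform(m)
    subset_series(v, genes = filter_expressed(v))
  }
  va <- prep(sp$matrix_a); vb <- prep(sp$matrix_b)
  net_a <- build_network(va, clr_transform(mutual_information(va)), 3.5)
  net_b <- build_network(vb, clr_transform(mutual_information(vb)), 3.5)
  rep <- conservation_report(net_a, net_b, sp$truth$orthologs,
                             sp$truth$seeds$seed_a,
                             threshold_a = 5, threshold_b = 3.5)
  expect_identical(rep$verdict == "diverged", sp$truth$seeds$diverged)
  expect_equal(sum(rep$verdict == "diverged"), 1)
})
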