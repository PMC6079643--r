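test_that("variance filter keeps exactly the recomputed set under both readings", {
  set.seed(8)
  X <- matrix(stats::rnorm(40 * 10, sd = rep(c(0.5, 1.5), each = 20)), 40, 10)
  rownames(X) <- sprintf("G%03d", 1:40)
  s <- mk_series(X)
  v <- apply(X, 1, stats::var)
  expect_identical(variance_filter(s, 1, "variance"), rownames(X)[v > 1])
  expect_identical(variance_filter(s, 1.2, "sd"), rownames(X)[v > 1.2^2])
  # constant gene dropped, strongly alternating gene kept, either way
  Y <- rbind(const = rep(3, 10), alt = rep(c(0, 10), 5))
  sy <- mk_series(Y); rownames(sy$values) <- c("const", "alt")
  expect_identical(variance_filter(sy, 1, "variance"), "alt")
  expect_identical(variance_filter(sy, 1, "sd"), "alt")
  expect_error(variance_filter(mk_series(X[, 1, drop = FALSE])), "single")
})

test_that("two planted correlation blocks are perfectly recovered at k = 2", {
  set.seed(15)
  n <- 24
  base1 <- stats::rnorm(n); base2 <- stats::rnorm(n)
  X <- rbind(t(sapply(1:10, function(i) base1 + stats::rnorm(n, sd = 0.2))),
             t(sapply(1:10, function(i) base2 + stats::rnorm(n, sd = 0.2))))
  s <- mk_series(X)
  cl <- cluster_genes(s, k = 2)
  truth <- rep(1:2, each = 10)
  expect_equal(mclust::adjustedRandIndex(cl$gene_labels, truth), 1)
  expect_equal(length(cl$gene_dendrogram$height), nrow(X) - 1)
})

test_that("clustering degenerate cases behave", {
  set.seed(2)
  X <- matrix(stats::rnorm(5 * 12), 5, 12)
  s <- mk_series(X)
  # k = n gives singletons
  cl <- cluster_genes(s, k = 5)
  expect_equal(sort(unname(cl$gene_labels)), 1:5)
  expect_error(cluster_genes(s, k = 6), "exceeds")
  # constant genes are named in the error
  Xc <- rbind(X, flat = rep(1, 12))
  sc <- mk_series(Xc); rownames(sc$values)[6] <- "flat"
  expect_error(cluster_genes(sc, k = 2), "flat")
})

test_that("duplicating every gene leaves the originals' partition intact", {
  set.seed(44)
  n <- 20
  base1 <- stats::rnorm(n); base2 <- stats::rnorm(n)
  X <- rbind(t(sapply(1:6, function(i) base1 + stats::rnorm(n, sd = 0.3))),
             t(sapply(1:6, function(i) base2 + stats::rnorm(n, sd = 0.3))))
  rownames(X) <- sprintf("G%03d", 1:12)
  X2 <- rbind(X, X)
  rownames(X2) <- c(rownames(X), paste0(rownames(X), "_dup"))
  cl1 <- cluster_genes(mk_series(X), k = 2)
  cl2 <- cluster_genes(mk_series(X2), k = 2)
  a <- cl1$gene_labels
  b <- cl2$gene_labels[names(a)]
  expect_equal(mclust::adjustedRandIndex(a, b), 1)
})

test_that("clustering is invariant to positive per-gene affine rescaling", {
  set.seed(31)
  n <- 18
  base1 <- stats::rnorm(n); base2 <- stats::rnorm(n)
  X <- rbind(t(sapply(1:5, function(i) base1 + stats::rnorm(n, sd = 0.3))),
             t(sapply(1:5, function(i) base2 + stats::rnorm(n, sd = 0.3))))
  rownames(X) <- sprintf("G%03d", 1:10)
  slope <- stats::runif(10, 0.5, 3)
  shift <- stats::rnorm(10, sd = 4)
  X2 <- X * slope + shift
  cl1 <- cluster_genes(mk_series(X), k = 2)
  cl2 <- cluster_genes(mk_series(X2), k = 2)
  expect_equal(mclust::adjustedRandIndex(cl1$gene_labels,
                                         cl2$gene_labels[names(cl1$gene_labels)]),
               1)
})

test_that("per-gene scaling standardises rows and errors on constants", {
  set.seed(12)
  X <- matrix(stats::rnorm(6 * 10, mean = 5, sd = 2), 6, 10)
  s <- mk_series(X)
  sc <- scale_per_gene(s)
  expect_equal(unname(rowMeans(sc)), rep(0, 6))
  expect_equal(unname(apply(sc, 1, stats::sd)), rep(1, 6))
  # identity on already-standardised rows
  Z <- t(scale(t(X)))
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  sz <- mk_series(Z)
  expect_equal(unclass(scale_per_gene(sz)), unclass(Z), tolerance = 1e-12,
               ignore_attr = TRUE)
  Xc <- rbind(X, flat = rep(2, 10))
  sc2 <- mk_series(Xc); rownames(sc2$values)[7] <- "flat"
  expect_error(scale_per_gene(sc2), "flat")
  # oracle recomputation on a random matrix
  want <- t(apply(X, 1, function(r) (r - mean(r)) / stats::sd(r)))
  dimnames(want) <- dimnames(s$values)
  expect_equal(scale_per_gene(s), want, tolerance = 1e-12)
})

test_that("expression domains follow the within-4%-of-maximum rule", {
  X <- rbind(g1 = c(1, 5, 4.9, 2), g2 = c(2, 2, 2, 2))
  s <- mk_series(X); rownames(s$values) <- c("g1", "g2")
  d <- assign_expression_domain(s, 0.04)
  expect_setequal(d$assignments$g1, sample_ids(s)[2:3])  # cutoff 4.8
  expect_setequal(d$assignments$g2, sample_ids(s))       # constant positive
  # zero tolerance keeps only the argmax
  d0 <- assign_expression_domain(s, 0)
  expect_identical(d0$assignments$g1, sample_ids(s)[2])
  expect_error(assign_expression_domain(s, 1), "tolerance")
  expect_error(assign_expression_domain(s, -0.1), "tolerance")
  # non-positive maximum genes are skipped and reported
  Xn <- rbind(ok = c(0, 1, 2, 0), dead = c(0, 0, 0, 0))
  sn <- mk_series(Xn); rownames(sn$values) <- c("ok", "dead")
  dn <- assign_expression_domain(sn)
  expect_identical(dn$skipped, "dead")
  expect_false("dead" %in% names(dn$assignments))
})

test_that("domain sets are non-empty and shrink as tolerance decreases", {
  set.seed(77)
  X <- matrix(stats::runif(200 * 10, 0, 10), 200, 10)
  s <- mk_series(X)
  d_lo <- assign_expression_domain(s, 0.01)
  d_hi <- assign_expression_domain(s, 0.10)
  expect_true(all(lengths(d_lo$assignments) >= 1))
  for (gn in names(d_lo$assignments)) {
    expect_true(all(d_lo$assignments[[gn]] %in% d_hi$assignments[[gn]]))
  }
})

test_that("planted developmental clusters are recovered on the filtered set", {
  cfg <- simulation_config(rng_seed = 1)   # 600 genes, 6 clusters, 8x base
  sim <- simulate_series(cfg)
  vst <- vst_transform(sim$matrix)
  expressed <- filter_expressed(vst)
  vf <- subset_series(vst, genes = expressed)
  kept <- variance_filter(vf)
  cl <- cluster_genes(vf, kept, k = 6)
  truth <- sim$truth$cluster_label[kept]
  expect_gte(mclust::adjustedRandIndex(cl$gene_labels, truth), 0.9)
  # noise genes cohere less than planted clusters
  noise <- names(sim$truth$cluster_label)[sim$truth$cluster_label == "z"]
  mean_cor <- function(genes) {
    if (length(genes) < 2) return(NA_real_)
    cm <- stats::cor(t(vst$values[genes, ]))
    mean(cm[upper.tri(cm)])
  }
  planted_cor <- vapply(letters[1:6], function(l) {
    mean_cor(names(sim$truth$cluster_label)[sim$truth$cluster_label == l])
  }, numeric(1))
  expect_lt(mean_cor(noise), min(planted_cor))
})
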