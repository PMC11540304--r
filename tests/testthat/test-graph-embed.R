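# HVG selection, PCA/KNN graph, Leiden, UMAP and the rank-based marker
# statistic.

test_that("designed high-dispersion genes are selected as HVGs", {
  set.seed(17)
  n_cells <- 300
  base <- matrix(rpois(100 * n_cells, 5), 100, n_cells,
                 dimnames = list(sprintf("G%03d", 1:100),
                                 sprintf("c%03d", 1:n_cells)))
  hi <- sprintf("G%03d", 1:10)
  # independently bimodal expression = high dispersion at unchanged mean
  base[hi, ] <- rpois(10 * n_cells,
                      5 * (rbinom(10 * n_cells, 1, 0.5) + 0.5))
  hvgs <- select_hvgs(Matrix::Matrix(base, sparse = TRUE),
                      n_hvgs = 20, min_cells = 10)
  expect_true(all(hi %in% hvgs))
})

test_that("genes below the detection floor are never selected", {
  set.seed(18)
  m <- matrix(rpois(50 * 100, 3), 50, 100,
              dimnames = list(sprintf("G%02d", 1:50),
                              sprintf("c%03d", 1:100)))
  m["G01", ] <- 0
  m["G01", 1:19] <- 1000   # huge dispersion but detected in 19 < 20 cells
  hvgs <- suppressWarnings(
    select_hvgs(Matrix::Matrix(m, sparse = TRUE), 50, min_cells = 20))
  expect_false("G01" %in% hvgs)
})

test_that("KNN graph equals brute-force pairwise search", {
  ref <- small_reference()
  sub <- ref$rna[, 1:200]
  hvgs <- select_hvgs(sub, 100, 10)
  g <- build_graph(sub, hvgs, graph_params(n_hvgs = 100, min_cells = 10,
                                           n_pcs = 10, k_neighbors = 6))
  oracle <- brute_knn(g$pcs, g$pcs, 7)[, -1]  # drop self
  for (i in seq_len(nrow(oracle))) {
    expect_setequal(g$knn$index[i, ], oracle[i, ])
  }
})

test_that("neighbors stay within their own blob for separated data", {
  set.seed(19)
  blob <- function(center, n) {
    m <- matrix(rpois(40 * n, rep(center, n)), 40, n)
    rownames(m) <- sprintf("G%02d", 1:40)
    m
  }
  x <- cbind(blob(rep(c(50, 2), each = 20), 40),
             blob(rep(c(2, 50), each = 20), 40))
  colnames(x) <- sprintf("c%02d", 1:80)
  g <- build_graph(Matrix::Matrix(x, sparse = TRUE), rownames(x),
                   graph_params(n_hvgs = 40, min_cells = 5, n_pcs = 5,
                                k_neighbors = 5))
  same_blob <- outer(rep(1:2, each = 40), rep(1:2, each = 40), "==")
  expect_true(all(same_blob[cbind(rep(1:80, 5), as.vector(g$knn$index))]))
})

test_that("restricting the fit to all cells changes nothing", {
  ref <- small_reference()
  sub <- ref$rna[, 1:120]
  hvgs <- select_hvgs(sub, 80, 10)
  params <- graph_params(n_hvgs = 80, min_cells = 10, n_pcs = 8,
                         k_neighbors = 5)
  g0 <- build_graph(sub, hvgs, params)
  g1 <- build_graph(sub, hvgs, params, fit_cells = rep(TRUE, 120))
  expect_equal(g0$pcs, g1$pcs)
  expect_identical(g0$knn$index, g1$knn$index)
})

test_that("a duplicated cell projects onto its source's coordinates", {
  ref <- small_reference()
  sub <- ref$rna[, 1:100]
  hvgs <- select_hvgs(sub, 80, 10)
  params <- graph_params(n_hvgs = 80, min_cells = 10, n_pcs = 8,
                         k_neighbors = 5)
  g0 <- build_graph(sub, hvgs, params)
  dup <- cbind(sub, dup_cell = sub[, 7])
  g1 <- suppressWarnings(
    build_graph(dup, hvgs, params, fit_cells = colnames(sub)))
  expect_equal(unname(g1$pcs[1:100, ]), unname(g0$pcs))
  expect_equal(unname(g1$pcs[101, ]), unname(g0$pcs[7, ]))
})

test_that("leiden separates disconnected cliques and ignores cell order", {
  g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  cl <- leiden_cluster(g, resolution = 1, seed = 1)
  expect_equal(nlevels(cl), 2)
  expect_equal(length(unique(cl[1:10])), 1)

  ref <- small_reference()
  hvgs <- select_hvgs(ref$rna, 150, 10)
  params <- graph_params(n_hvgs = 150, min_cells = 10, n_pcs = 10,
                         k_neighbors = 8)
  cl1 <- leiden_cluster(build_graph(ref$rna, hvgs, params), 1, seed = 1)
  perm <- sample(ncol(ref$rna))
  cl2 <- leiden_cluster(build_graph(ref$rna[, perm], hvgs, params), 1,
                        seed = 1)
  # identical partitions up to label renaming
  tab <- table(cl1[perm], cl2)
  expect_equal(sum(apply(tab, 1, max)), ncol(ref$rna))
})

test_that("umap is deterministic under a fixed seed and separates blobs", {
  set.seed(20)
  x <- rbind(matrix(rnorm(200, 0), 50), matrix(rnorm(200, 8), 50))
  params <- graph_params(k_neighbors = 10, umap_epochs = 200)
  e1 <- umap_embed(x, params, seed = 3)
  e2 <- umap_embed(x, params, seed = 3)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
  d <- as.matrix(dist(e1))
  intra <- mean(d[1:50, 1:50])
  inter <- mean(d[1:50, 51:100])
  expect_gt(inter, intra)
})

test_that("marker specificity matches hand enumeration and sums to one", {
  # 3 cells, 2 genes, 2 clusters; ranks within each cell (ties averaged)
  m <- matrix(c(5, 1,
                4, 2,
                0, 3), nrow = 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  clusters <- c("X", "X", "Y")
  spec <- marker_specificity(m, clusters)
  # per-cell ranks: c1 gA=2 gB=1; c2 gA=2 gB=1; c3 gA=1 gB=2
  # mean ranks: gA X=2 Y=1; gB X=1 Y=2
  expect_equal(spec["gA", "X"], 2 / 3)
  expect_equal(spec["gA", "Y"], 1 / 3)
  expect_equal(spec["gB", "X"], 1 / 3)
  expect_equal(spec["gB", "Y"], 2 / 3)

  ref <- small_reference()
  spec2 <- marker_specificity(ref$rna[1:50, ], ref$truth$cluster)
  expect_equal(unname(rowSums(spec2)), rep(1, 50), tolerance = 1e-9)
})

test_that("a gene expressed in only one cluster is specific to it", {
  m <- matrix(rpois(40 * 2, 3), 2, 40,
              dimnames = list(c("target", "other"), sprintf("c%02d", 1:40)))
  m["target", 1:20] <- 50
  m["target", 21:40] <- 0
  spec <- marker_specificity(m, rep(c("A", "B"), each = 20))
  expect_gt(spec["target", "A"], 0.5)
  top <- top_markers(spec, n = 1)
  expect_identical(top$A, "target")
})
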