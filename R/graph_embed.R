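# HVG selection, normalization + PCA, KNN graph, Leiden clustering, UMAP
# embedding, and the rank-based marker-specificity statistic.

#' Graph/embedding parameters
#'
#' Defaults are the CML-sample settings: 2000 HVGs with min_cells = 50
#' (the CML8 dialect uses 1000/30), top 20 principal components, 11
#' neighbors, Leiden resolution 1 (0.76 for the normal bone marrow
#' reference), UMAP min_dist 1 / spread 2 / 2000 epochs (500 for the
#' primitive-merge dialect).
#'
#' @param n_hvgs,min_cells HVG selection settings.
#' @param n_pcs Principal components retained.
#' @param k_neighbors KNN graph degree.
#' @param leiden_resolution Community-detection resolution.
#' @param umap_min_dist,umap_spread,umap_epochs UMAP layout settings.
#' @export
graph_params <- function(n_hvgs = 2000, min_cells = 50, n_pcs = 20,
                         k_neighbors = 11, leiden_resolution = 1,
                         umap_min_dist = 1, umap_spread = 2,
                         umap_epochs = 2000) {
  stopifnot(n_hvgs > 0, min_cells > 0, n_pcs > 0, n_pcs <= n_hvgs,
            k_neighbors > 0, leiden_resolution > 0)
  list(n_hvgs = n_hvgs, min_cells = min_cells, n_pcs = n_pcs,
       k_neighbors = k_neighbors, leiden_resolution = leiden_resolution,
       umap_min_dist = umap_min_dist, umap_spread = umap_spread,
       umap_epochs = umap_epochs)
}

#' Select highly variable genes
#'
#' Genes detected in fewer than `min_cells` cells are ineligible. Eligible
#' genes are scored by mean-corrected dispersion of library-size-normalized
#' log counts: the dispersion (variance/mean) is z-scored within
#' mean-expression bins (robustly, against the bin median and MAD), so
#' genes are ranked against peers of comparable abundance. The top
#' `n_hvgs` by normalized dispersion are returned.
#'
#' @param rna Features x cells count matrix.
#' @param n_hvgs Number of genes to return.
#' @param min_cells Detection eligibility cutoff.
#' @param exclude Gene names excluded regardless of dispersion (e.g.
#'   sex-chromosome-linked genes in the primitive-merge dialect).
#' @param n_bins Mean-expression bins for the trend (default 20).
#' @return Character vector of gene names ordered by decreasing residual.
#' @export
select_hvgs <- function(rna, n_hvgs = 2000, min_cells = 50,
                        exclude = character(0), n_bins = 20) {
  if (ncol(rna) == 0 || nrow(rna) == 0) stop("empty matrix")
  detected <- Matrix::rowSums(rna > 0)
  norm <- normalize_counts(rna)
  mu <- Matrix::rowMeans(norm)
  v <- matrixStats::rowVars(as.matrix(norm))
  eligible <- detected >= min_cells & mu > 0 &
    !(rownames(rna) %in% exclude)
  disp <- ifelse(mu > 0, v / mu, 0)
  # keep >= 20 genes per bin so the bin statistics are stable
  n_bins <- max(1, min(n_bins, floor(sum(eligible) / 20)))
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  resid <- disp
  for (b in unique(bins[eligible])) {
    sel <- eligible & bins == b
    scale <- stats::mad(disp[sel])
    if (scale <= 0) scale <- stats::sd(disp[sel])
    if (!is.finite(scale) || scale <= 0) scale <- 1
    resid[sel] <- (disp[sel] - stats::median(disp[sel])) / scale
  }
  cand <- rownames(rna)[eligible]
  cand <- cand[order(resid[eligible], decreasing = TRUE)]
  if (length(cand) < n_hvgs) {
    warning("only ", length(cand), " eligible genes; returning all")
    return(cand)
  }
  utils::head(cand, n_hvgs)
}

#' Normalize, reduce and build the KNN graph
#'
#' Counts are library-size normalized to the median library, log1p
#' transformed, restricted to the HVGs, z-scaled per gene, and projected
#' onto the top `n_pcs` principal components. Components whose eigenvalue
#' falls below the Marchenko-Pastur noise edge are discarded (a
#' scran-style denoising step: Euclidean distances over pure-noise
#' components only dilute neighborhood structure), so at most `n_pcs` and
#' at least 2 components are kept. When `fit_cells` is given,
#' normalization statistics and the PCA are fitted on that subset only and
#' applied to all cells (used when control cells are projected into a
#' CML-fitted space). The KNN graph connects each cell to its
#' `k_neighbors` nearest cells by Euclidean distance in PC space.
#'
#' @param rna Features x cells count matrix.
#' @param hvgs Gene names to use (subset of `rownames(rna)`).
#' @param params A [graph_params()] list.
#' @param fit_cells Optional logical mask or cell names: the subset on
#'   which scaling statistics and PCA loadings are fitted.
#' @param trim_pcs Discard components below the Marchenko-Pastur noise
#'   edge (default TRUE).
#' @return A `cell_graph` list: `pcs` (cells x kept components), `knn`
#'   (`index`/`distance` matrices), plus the fitted statistics
#'   (`hvgs`, `centers`, `sds`, `rotation`, `lib_target`).
#' @export
build_graph <- function(rna, hvgs, params = graph_params(), fit_cells = NULL,
                        trim_pcs = TRUE) {
  if (length(setdiff(hvgs, rownames(rna)))) stop("hvgs must be features of rna")
  n <- ncol(rna)
  fit <- if (is.null(fit_cells)) rep(TRUE, n) else {
    if (is.character(fit_cells)) colnames(rna) %in% fit_cells else fit_cells
  }
  if (!any(fit)) stop("fit_cells selects no cells")
  lib_target <- stats::median(Matrix::colSums(rna)[fit])
  norm <- as.matrix(normalize_counts(rna[hvgs, , drop = FALSE],
                                     target = lib_target))
  centers <- rowMeans(norm[, fit, drop = FALSE])
  sds <- matrixStats::rowSds(norm[, fit, drop = FALSE])
  z <- .zscale_rows(norm, centers, sds)
  n_pcs <- min(params$n_pcs, sum(fit) - 1, length(hvgs))
  if (n_pcs < params$n_pcs)
    warning("n_pcs reduced to ", n_pcs, " (rank limit)")
  pca <- stats::prcomp(t(z[, fit, drop = FALSE]), center = TRUE,
                       scale. = FALSE, rank. = n_pcs)
  rotation <- pca$rotation
  if (trim_pcs) {
    # Parallel analysis: the noise edge is the top eigenvalue after
    # permuting every gene independently across the fit cells, which
    # preserves the (selection-biased) per-gene marginals but destroys
    # all gene-gene structure.
    ev <- pca$sdev^2
    edge <- 1.05 * .permuted_top_eigenvalue(z[, fit, drop = FALSE])
    keep <- max(2, min(ncol(rotation), sum(ev > edge)))
    rotation <- rotation[, seq_len(keep), drop = FALSE]
  }
  pcs <- (t(z) - matrix(pca$center, n, length(hvgs), byrow = TRUE)) %*%
    rotation
  rownames(pcs) <- colnames(rna)
  k <- min(params$k_neighbors, n - 1)
  knn <- BiocNeighbors::findKNN(pcs, k = k)
  structure(list(pcs = pcs, knn = knn, hvgs = hvgs, centers = centers,
                 sds = sds, pca_center = pca$center, rotation = rotation,
                 lib_target = lib_target, params = params),
            class = "cell_graph")
}

# Top eigenvalue (sample covariance scale) of the row-permuted matrix,
# computed with a private RNG stream so callers' seeds are untouched.
.permuted_top_eigenvalue <- function(z_fit) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(703813L)
  x <- t(apply(z_fit, 1, sample))       # permute each gene across cells
  x <- t(x)                             # cells x genes
  x <- sweep(x, 2, colMeans(x))
  sv <- irlba::irlba(x, nv = 1)
  sv$d[1]^2 / (nrow(x) - 1)
}

# igraph from a KNN index matrix (undirected, deduplicated).
.knn_igraph <- function(knn, n) {
  k <- ncol(knn$index)
  edges <- cbind(rep(seq_len(n), k), as.vector(knn$index))
  igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
}

# Weighted igraph with UMAP-style smooth-KNN edge weights: each cell's
# edges decay exponentially relative to its local distance scale
# (w = exp(-(d - rho)/sigma)) and the directed weights are combined by
# fuzzy union. Long between-population edges get small weights, which is
# what lets low-resolution community detection see the partition.
.knn_fuzzy_igraph <- function(knn, n) {
  idx <- knn$index
  d <- knn$distance
  k <- ncol(idx)
  rho <- d[, 1]
  sigma <- pmax(rowMeans(d) - rho, 1e-6)
  w <- exp(-sweep(sweep(d, 1, rho), 1, sigma, "/"))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                            x = as.vector(w), dims = c(n, n))
  S <- A + Matrix::t(A) - A * Matrix::t(A)
  igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Leiden community detection on the KNN graph
#'
#' Runs Leiden with the modularity objective on the smooth-KNN weighted
#' graph (see the package vignette for the edge-weight scheme).
#'
#' @param graph A `cell_graph` from [build_graph()] (or an igraph object,
#'   used as supplied).
#' @param resolution Modularity resolution (1 for CML samples, 0.76 for
#'   the reference, 0.1 for the coarse primitive merge).
#' @param seed Integer seed for reproducibility.
#' @param n_iterations Leiden refinement iterations.
#' @return Factor of per-cell cluster labels.
#' @export
leiden_cluster <- function(graph, resolution = 1, seed = 1L,
                           n_iterations = 10) {
  g <- if (inherits(graph, "cell_graph"))
    .knn_fuzzy_igraph(graph$knn, nrow(graph$pcs)) else graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(seed)
  com <- igraph::cluster_leiden(g, objective_function = "modularity",
                                resolution = resolution,
                                n_iterations = n_iterations)
  labels <- factor(igraph::membership(com))
  if (inherits(graph, "cell_graph")) names(labels) <- rownames(graph$pcs)
  labels
}

#' UMAP embedding of cells
#'
#' @param graph A `cell_graph` (its PC coordinates are embedded) or a
#'   numeric cells x dims matrix.
#' @param params A [graph_params()] list (min_dist, spread, epochs,
#'   k_neighbors are used).
#' @param seed Integer seed; fixed seed gives identical coordinates.
#' @return Cells x 2 coordinate matrix.
#' @export
umap_embed <- function(graph, params = graph_params(), seed = 1L) {
  x <- if (inherits(graph, "cell_graph")) graph$pcs else as.matrix(graph)
  if (nrow(x) < 3) stop("need at least 3 cells to embed")
  set.seed(seed)
  emb <- uwot::umap(x, n_neighbors = min(params$k_neighbors, nrow(x) - 1),
                    min_dist = params$umap_min_dist,
                    spread = params$umap_spread,
                    n_epochs = params$umap_epochs,
                    n_threads = 1, n_sgd_threads = 0, batch = FALSE)
  rownames(emb) <- rownames(x)
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}

#' Rank-based marker specificity per cluster
#'
#' Within each cell, genes are ranked by expression (average ranks for
#' ties, higher expression = higher rank). Per gene and cluster the mean
#' rank over the cluster's cells is computed; the specificity of a gene for
#' a cluster is its mean rank there divided by the sum of its mean ranks
#' across clusters, so each gene's specificities sum to 1.
#'
#' @param rna Features x cells expression matrix (counts or normalized).
#' @param clusters Per-cell cluster labels.
#' @return Genes x clusters matrix of specificities.
#' @export
marker_specificity <- function(rna, clusters) {
  clusters <- as.character(clusters)
  keep <- table(clusters)
  if (length(keep) < 2) stop("need at least 2 clusters")
  ranks <- matrixStats::colRanks(as.matrix(rna), ties.method = "average",
                                 preserveShape = TRUE)
  dimnames(ranks) <- dimnames(rna)
  levs <- names(keep)
  mean_rank <- vapply(levs, function(cl)
    rowMeans(ranks[, clusters == cl, drop = FALSE]), numeric(nrow(rna)))
  spec <- mean_rank / rowSums(mean_rank)
  rownames(spec) <- rownames(rna)
  spec
}

#' Top marker genes per cluster
#'
#' @param specificity Genes x clusters matrix from [marker_specificity()].
#' @param n Genes per cluster (default 10, the annotation setting).
#' @return Named list of character vectors, one per cluster.
#' @export
top_markers <- function(specificity, n = 10) {
  lapply(stats::setNames(colnames(specificity), colnames(specificity)),
         function(cl) {
           ord <- order(specificity[, cl], decreasing = TRUE)
           utils::head(rownames(specificity)[ord], n)
         })
}
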