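# Reference projection: normalize query cells with the reference's
# statistics, project with the reference PCA loadings, match to nearest
# reference cells, transfer labels by thresholded weighted vote, and score
# how often each reference cell is hit.

#' Build a reference model for projection
#'
#' Fits HVGs, normalization statistics, PCA loadings and the reference PC
#' coordinates on a labeled reference, packaging everything a query needs
#' for projection.
#'
#' @param rna Features x cells reference counts.
#' @param labels Per-cell reference cluster labels.
#' @param params A [graph_params()] list.
#' @param hvgs Optional precomputed HVG list (default: [select_hvgs()]
#'   with the params settings).
#' @return A `reference_model` list.
#' @export
build_reference <- function(rna, labels, params = graph_params(),
                            hvgs = NULL) {
  if (length(labels) != ncol(rna)) stop("every reference cell must be labeled")
  if (is.null(hvgs))
    hvgs <- select_hvgs(rna, n_hvgs = params$n_hvgs,
                        min_cells = params$min_cells)
  graph <- build_graph(rna, hvgs, params)
  structure(list(hvgs = graph$hvgs, centers = graph$centers,
                 sds = graph$sds, pca_center = graph$pca_center,
                 rotation = graph$rotation, lib_target = graph$lib_target,
                 ref_pcs = graph$pcs,
                 labels = stats::setNames(as.character(labels),
                                          colnames(rna))),
            class = "reference_model")
}

#' Project query cells onto a reference
#'
#' Query counts are normalized with the reference's library target and
#' per-gene statistics, projected with the reference loadings, and matched
#' to their `n_neighbors` nearest reference cells in PC space. Neighbor
#' weights are normalized inverse distances,
#' \eqn{w_j = (1/(d_j+\epsilon)) / \sum_l 1/(d_l+\epsilon)} with
#' \eqn{\epsilon = 10^{-9}}, so they sum to 1 per query cell.
#'
#' Reference HVGs absent from the query are zero-filled (with a warning);
#' if fewer than 90% of the reference HVGs are present the query is
#' rejected. Query genes outside the HVG list are ignored.
#'
#' @param reference A `reference_model` from [build_reference()].
#' @param query_rna Features x cells query counts.
#' @param n_neighbors Reference neighbors per query cell (default 5).
#' @return A `projection_result` list: `index`, `distance`, `weights`
#'   (query x k matrices) and `ref_labels`.
#' @export
map_cells <- function(reference, query_rna, n_neighbors = 5) {
  stopifnot(inherits(reference, "reference_model"))
  if (ncol(query_rna) == 0) {
    return(structure(list(index = matrix(0L, 0, n_neighbors),
                          distance = matrix(0, 0, n_neighbors),
                          weights = matrix(0, 0, n_neighbors),
                          ref_labels = reference$labels),
                     class = "projection_result"))
  }
  shared <- intersect(reference$hvgs, rownames(query_rna))
  if (length(shared) < 0.9 * length(reference$hvgs))
    stop("query shares fewer than 90% of the reference HVGs")
  norm <- as.matrix(normalize_counts(query_rna[shared, , drop = FALSE],
                                     target = reference$lib_target))
  full <- matrix(0, length(reference$hvgs), ncol(query_rna),
                 dimnames = list(reference$hvgs, colnames(query_rna)))
  full[shared, ] <- norm
  if (length(shared) < length(reference$hvgs))
    warning(length(reference$hvgs) - length(shared),
            " reference HVGs missing from query; imputed as zero")
  z <- .zscale_rows(full, reference$centers, reference$sds)
  pcs <- (t(z) - matrix(reference$pca_center, ncol(query_rna),
                        length(reference$hvgs), byrow = TRUE)) %*%
    reference$rotation
  k <- min(n_neighbors, nrow(reference$ref_pcs))
  knn <- BiocNeighbors::queryKNN(reference$ref_pcs, pcs, k = k)
  eps <- 1e-9
  w <- 1 / (knn$distance + eps)
  w <- w / rowSums(w)
  rownames(knn$index) <- rownames(knn$distance) <- rownames(w) <-
    colnames(query_rna)
  structure(list(index = knn$index, distance = knn$distance, weights = w,
                 ref_labels = reference$labels),
            class = "projection_result")
}

#' Transfer reference labels by thresholded weighted vote
#'
#' Neighbor weights are summed by reference cluster per query cell; the top
#' cluster is assigned iff its summed weight strictly exceeds `threshold`
#' (default 0.5: more than half of the total weight from the top-matched
#' reference cells must agree), otherwise the cell abstains (`NA`).
#'
#' @param projection A `projection_result` from [map_cells()].
#' @param ref_labels Optional label override (defaults to the labels stored
#'   in the projection).
#' @param threshold Weight-majority threshold in `[0, 1]`.
#' @return Named character vector of transferred labels with `NA`
#'   abstentions.
#' @export
transfer_labels <- function(projection, ref_labels = NULL, threshold = 0.5) {
  stopifnot(inherits(projection, "projection_result"))
  labels <- if (is.null(ref_labels)) projection$ref_labels else
    stats::setNames(as.character(ref_labels), names(projection$ref_labels))
  nq <- nrow(projection$index)
  out <- rep(NA_character_, nq)
  for (i in seq_len(nq)) {
    lab <- labels[projection$index[i, ]]
    agg <- tapply(projection$weights[i, ], lab, sum)
    if (max(agg) > threshold) out[i] <- names(agg)[which.max(agg)]
  }
  names(out) <- rownames(projection$index)
  out
}

#' Per-reference-cell mapping score
#'
#' Counts how often each reference cell appears among the top neighbors of
#' the projected query cells, normalized so the mean score over reference
#' cells is 1: \eqn{score_r = count_r \cdot n_{ref} / (k \cdot n_{query})}.
#' Scores are used to scale reference point sizes in embeddings.
#'
#' @param projection A `projection_result`.
#' @param n_reference Number of reference cells.
#' @return Numeric vector of length `n_reference`.
#' @export
mapping_score <- function(projection, n_reference) {
  stopifnot(inherits(projection, "projection_result"))
  if (nrow(projection$index) == 0) stop("empty projection")
  counts <- tabulate(as.vector(projection$index), nbins = n_reference)
  k <- ncol(projection$index)
  counts * n_reference / (k * nrow(projection$index))
}
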