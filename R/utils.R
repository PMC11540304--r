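# Shared helpers: count normalization and small numeric utilities.
# All count matrices in this package are features x cells (10x convention).

#' Library-size normalize and log-transform counts
#'
#' Scales each cell's counts to a common library size (the median across
#' cells unless `target` is given) and applies `log1p`. This is the
#' normalization contract used before HVG selection, PCA and signature
#' scoring throughout the package.
#'
#' @param counts A features x cells matrix (dense or `Matrix` sparse).
#' @param target Target library size; defaults to the median of the cell
#'   totals. Stored references pass their own target so queries are scaled
#'   consistently.
#' @param log Apply `log1p` after scaling (default `TRUE`).
#' @return A matrix of the same shape; sparse input stays sparse.
#' @export
normalize_counts <- function(counts, target = NULL, log = TRUE) {
  totals <- Matrix::colSums(counts)
  if (is.null(target)) target <- stats::median(totals[totals > 0])
  sf <- ifelse(totals > 0, target / totals, 0)
  out <- counts %*% Matrix::Diagonal(x = sf)
  dimnames(out) <- dimnames(counts)
  if (log) out <- log1p(out)
  out
}

# Dense per-gene z-scaling with externally supplied statistics (constant
# genes become all-zero rows rather than NaN).
.zscale_rows <- function(x, centers, sds) {
  x <- as.matrix(x)
  sds <- ifelse(sds > 0, sds, Inf)
  (x - centers) / sds
}

.as_dgc <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

# Deterministic child seed derived from a base seed and a stream index,
# kept inside 32-bit integer range.
.child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 9973) %% 2147483629L)
}
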