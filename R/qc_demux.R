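# Cell QC filtering, hashtag demultiplexing by Otsu thresholding, and
# HTO/RNA cluster-overlap doublet exclusion.

#' QC thresholds
#'
#' Defaults follow the CML sample settings: cells with fewer than 1000 or
#' more than 9000 detected genes, or a mitochondrial UMI fraction above
#' `max_mito_fraction` (0.11 for CML samples; 0.06 is the normal bone
#' marrow reference setting), are excluded.
#'
#' @param min_genes,max_genes Detected-gene bounds (inclusive).
#' @param max_mito_fraction Maximum mitochondrial UMI fraction (inclusive).
#' @export
qc_thresholds <- function(min_genes = 1000, max_genes = 9000,
                          max_mito_fraction = 0.11) {
  stopifnot(min_genes > 0, min_genes < max_genes,
            max_mito_fraction > 0, max_mito_fraction < 1)
  list(min_genes = min_genes, max_genes = max_genes,
       max_mito_fraction = max_mito_fraction)
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' @param rna Features x cells count matrix.
#' @param thresholds A [qc_thresholds()] list.
#' @param mito_genes Mitochondrial gene identifiers; defaults to the
#'   `MT-`-prefixed features of `rna`.
#' @return Named logical mask over cells (`TRUE` = retained).
#' @export
filter_cells <- function(rna, thresholds = qc_thresholds(),
                         mito_genes = grep("^MT-", rownames(rna), value = TRUE)) {
  if (ncol(rna) == 0) {
    warning("empty matrix: no cells to filter")
    return(logical(0))
  }
  if (length(setdiff(mito_genes, rownames(rna))))
    stop("mito_genes contains features absent from the matrix")
  n_genes <- Matrix::colSums(rna > 0)
  totals <- Matrix::colSums(rna)
  mito <- if (length(mito_genes)) {
    Matrix::colSums(rna[mito_genes, , drop = FALSE])
  } else rep(0, ncol(rna))
  mito_frac <- ifelse(totals > 0, mito / totals, 0)
  mask <- n_genes >= thresholds$min_genes & n_genes <= thresholds$max_genes &
    mito_frac <= thresholds$max_mito_fraction
  names(mask) <- colnames(rna)
  mask
}

#' Otsu threshold for one hashtag's counts
#'
#' Pixel-style automatic thresholding on `log1p`-transformed counts binned
#' into a 256-bin histogram: the cut maximizing the between-class variance
#' is found by exhaustive search over the bin boundaries, relaxed downward
#' by `background_buffer` times the transformed range, and floored at
#' `override` times the transformed maximum. The cut is returned on the
#' original count scale.
#'
#' @param values Non-negative counts for one hashtag across cells.
#' @param background_buffer Downward relaxation as a fraction of the
#'   transformed range (default 0.1).
#' @param override Floor as a fraction of the transformed maximum
#'   (default 0.5).
#' @param n_bins Histogram bins (default 256).
#' @param relax Apply the buffer/override relaxation (default TRUE; FALSE
#'   returns the raw between-class-variance maximizer).
#' @return The cut value on the count scale, or `NA` when the input is
#'   constant ("no threshold": the caller treats all cells as background).
#' @export
otsu_threshold <- function(values, background_buffer = 0.1, override = 0.5,
                           n_bins = 256, relax = TRUE) {
  if (length(unique(values)) < 2) return(NA_real_)
  x <- log1p(as.numeric(values))
  lo <- min(x); hi <- max(x)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  n <- sum(counts)
  # Between-class variance for every candidate cut (class 0 = bins 1..k).
  w0 <- cumsum(counts) / n
  m0 <- cumsum(counts * mids) / pmax(cumsum(counts), 1)
  mt <- sum(counts * mids) / n
  w1 <- 1 - w0
  m1 <- ifelse(w1 > 0, (mt - w0 * m0) / w1, 0)
  bcv <- w0 * w1 * (m0 - m1)^2
  bcv[w0 == 0 | w1 == 0] <- 0
  k <- which.max(bcv)
  cut_t <- breaks[k + 1]
  if (relax) {
    cut_t <- cut_t - background_buffer * (hi - lo)
    if (cut_t < override * hi) cut_t <- override * hi
  }
  expm1(cut_t)
}

#' Demultiplex cells by hashtag counts
#'
#' Per hashtag, the cut is the fixed threshold when supplied, otherwise
#' [otsu_threshold()]. A cell is assigned hashtag `h` iff its count strictly
#' exceeds the cut for `h` and for no other hashtag; two or more exceedances
#' give `"multiplet"`, none `"unassigned"`.
#'
#' @param hto Hashtags x cells count matrix.
#' @param fixed_thresholds Optional named vector of per-hashtag cuts.
#' @param ... Passed to [otsu_threshold()].
#' @return List with `labels` (named character per cell) and `thresholds`.
#' @export
demultiplex <- function(hto, fixed_thresholds = NULL, ...) {
  if (nrow(hto) < 1) stop("hto must have at least one hashtag feature")
  tags <- rownames(hto)
  if (!is.null(fixed_thresholds)) {
    unknown <- setdiff(names(fixed_thresholds), tags)
    if (length(unknown))
      stop("fixed thresholds reference unknown hashtags: ",
           paste(unknown, collapse = ", "))
  }
  cuts <- vapply(tags, function(h) {
    if (!is.null(fixed_thresholds) && h %in% names(fixed_thresholds))
      return(as.numeric(fixed_thresholds[[h]]))
    otsu_threshold(as.numeric(hto[h, ]), ...)
  }, numeric(1))
  dense <- as.matrix(hto)
  # NA cut = "no threshold": that hashtag is all background.
  exceed <- sweep(dense, 1, ifelse(is.na(cuts), Inf, cuts), `>`)
  n_exc <- colSums(exceed)
  labels <- rep("unassigned", ncol(hto))
  labels[n_exc >= 2] <- "multiplet"
  one <- n_exc == 1
  labels[one] <- tags[apply(exceed[, one, drop = FALSE], 2, which.max)]
  names(labels) <- colnames(hto)
  list(labels = labels, thresholds = cuts)
}

#' Flag doublets by RNA-cluster / HTO-cluster overlap
#'
#' Cells are split into 2 groups in HTO space by agglomerative clustering
#' of a KNN graph built on CLR-normalized hashtag counts. For every pair of
#' an RNA cluster `r` and an HTO group `h`, if the overlap exceeds
#' `overlap_threshold` in both directions (`|r∩h|/|r|` and `|r∩h|/|h|`),
#' the cells in the intersection are flagged as doublets.
#'
#' @param rna_clusters Per-cell cluster labels (RNA side).
#' @param hto Hashtags x cells count matrix for the same cells.
#' @param overlap_threshold Reciprocal overlap proportion (default 0.7,
#'   strict exceedance).
#' @param k Neighbors for the HTO KNN graph (default 11).
#' @return Logical doublet mask over cells.
#' @export
exclude_hto_doublets <- function(rna_clusters, hto, overlap_threshold = 0.7,
                                 k = 11) {
  n <- ncol(hto)
  if (length(rna_clusters) != n)
    stop("rna_clusters must be defined for every cell in hto")
  if (n < 2) {
    warning("fewer than 2 cells: no doublet flags")
    return(rep(FALSE, n))
  }
  clr <- t(clr_normalize(hto))
  k_use <- min(k, n - 1)
  knn <- suppressWarnings(BiocNeighbors::findKNN(clr, k = k_use))
  edges <- cbind(rep(seq_len(n), k_use), as.vector(knn$index))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  com <- igraph::cluster_fast_greedy(g)
  hto_grp <- tryCatch(igraph::cut_at(com, no = 2),
                      error = function(e) igraph::membership(com),
                      warning = function(w) igraph::membership(com))
  flags <- rep(FALSE, n)
  for (r in unique(rna_clusters)) {
    in_r <- rna_clusters == r
    for (h in unique(hto_grp)) {
      in_h <- hto_grp == h
      inter <- in_r & in_h
      if (sum(inter) / sum(in_r) > overlap_threshold &&
          sum(inter) / sum(in_h) > overlap_threshold) {
        flags[inter] <- TRUE
      }
    }
  }
  names(flags) <- colnames(hto)
  flags
}
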