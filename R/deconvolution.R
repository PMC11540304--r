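# Reference-based bulk deconvolution: build a cluster signature matrix
# from labeled single-cell data, estimate mixing fractions per bulk sample
# by non-negative least squares on jointly quantile-normalized inputs, and
# compare responder groups.

#' Build a cluster signature matrix
#'
#' Per cluster, the mean library-size-normalized expression over the union
#' of each cluster's top `n_markers_per_cluster` genes by
#' [marker_specificity()]. Clusters below `min_cells` cells are excluded
#' with a warning.
#'
#' @param counts Features x cells single-cell count matrix.
#' @param labels Per-cell cluster labels.
#' @param n_markers_per_cluster Marker genes per cluster (default 50;
#'   clamped to the gene universe with a warning).
#' @param min_cells Minimum cluster size (default 10).
#' @return Genes x clusters signature matrix (linear normalized scale).
#' @export
build_signature_matrix <- function(counts, labels,
                                   n_markers_per_cluster = 50,
                                   min_cells = 10) {
  labels <- as.character(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warning("clusters below ", min_cells, " cells excluded: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    counts <- counts[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) stop("need at least 2 usable clusters")
  if (n_markers_per_cluster > nrow(counts)) {
    warning("n_markers_per_cluster exceeds the gene count; using all genes")
    n_markers_per_cluster <- nrow(counts)
  }
  norm <- normalize_counts(counts, log = FALSE)
  spec <- marker_specificity(norm, labels)
  markers <- unique(unlist(top_markers(spec, n_markers_per_cluster)))
  levs <- sort(unique(labels))
  sig <- vapply(levs, function(cl)
    Matrix::rowMeans(norm[markers, labels == cl, drop = FALSE]),
    numeric(length(markers)))
  rownames(sig) <- markers
  sig[rowSums(sig) > 0, , drop = FALSE]
}

# Quantile-normalize the columns of cbind(signature, bulk) jointly so the
# two platforms share one distribution (limma's implementation).
.joint_quantile <- function(sig, bulk) {
  both <- limma::normalizeQuantiles(cbind(sig, bulk))
  list(sig = both[, seq_len(ncol(sig)), drop = FALSE],
       bulk = both[, ncol(sig) + seq_len(ncol(bulk)), drop = FALSE])
}

#' Deconvolve bulk profiles into cluster fractions
#'
#' Per bulk sample, solves the non-negative least-squares problem
#' \eqn{\min_f \|b - S f\|_2, f \ge 0} on the shared genes (jointly
#' quantile-scaled by default) and normalizes the solution to sum to 1,
#' so each value is the estimated fraction of that cluster in the sample.
#'
#' @param bulk Genes x samples bulk expression matrix.
#' @param signature Genes x clusters signature matrix from
#'   [build_signature_matrix()].
#' @param quantile_scale Jointly quantile-normalize bulk and signature
#'   before solving (default TRUE). This mitigates platform scale mismatch
#'   (e.g. microarray bulk against a count-derived signature) at the cost
#'   of distorting exact linear mixtures; set FALSE for same-platform data.
#' @return Samples x clusters fraction matrix (rows sum to 1).
#' @export
deconvolve <- function(bulk, signature, quantile_scale = TRUE) {
  bulk <- as.matrix(bulk)
  shared <- intersect(rownames(signature), rownames(bulk))
  if (length(shared) < 0.5 * nrow(signature))
    stop("fewer than 50% of signature genes present in the bulk table")
  zero <- colSums(abs(bulk)) == 0
  if (any(zero))
    stop("all-zero bulk sample(s): ",
         paste(colnames(bulk)[zero], collapse = ", "))
  S <- as.matrix(signature[shared, , drop = FALSE])
  B <- bulk[shared, , drop = FALSE]
  # solve on common column totals (so scaling a sample never changes its
  # fractions), then convert the solution back to the original column units
  sig_tot <- colSums(S)
  S <- sweep(S, 2, sig_tot / 1e4, "/")
  B <- sweep(B, 2, colSums(B) / 1e4, "/")
  if (quantile_scale) {
    q <- .joint_quantile(S, B)
    S <- q$sig; B <- q$bulk
  }
  if (qr(S)$rank < ncol(S))
    warning("rank-deficient signature matrix; solution may not be unique")
  fracs <- t(vapply(seq_len(ncol(B)), function(j) {
    f <- pracma::lsqnonneg(S, B[, j])$x / sig_tot
    if (sum(f) == 0) f else f / sum(f)
  }, numeric(ncol(S))))
  dimnames(fracs) <- list(colnames(bulk), colnames(signature))
  fracs
}

#' Compare cluster fractions between responder groups
#'
#' Per cluster, the fold change of group mean fractions (group A over
#' group B) and a two-sided Welch t-test p-value, flagged significant at
#' p < `p_cut`.
#'
#' @param fractions Samples x clusters matrix from [deconvolve()].
#' @param groups Per-sample group labels (exactly 2 levels, each with at
#'   least 2 samples).
#' @param p_cut Significance level (default 0.05).
#' @return data.frame with `cluster`, `mean_a`, `mean_b`, `fold_change`,
#'   `pvalue`, `significant`; group A is the first factor level.
#' @export
compare_groups <- function(fractions, groups, p_cut = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly 2 groups")
  if (any(table(groups) < 2)) stop("both groups need >= 2 samples")
  a <- levels(groups)[1]
  rows <- lapply(colnames(fractions), function(cl) {
    xa <- fractions[groups == a, cl]
    xb <- fractions[groups != a, cl]
    p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) NA_real_ else
      stats::t.test(xa, xb)$p.value
    data.frame(cluster = cl, mean_a = mean(xa), mean_b = mean(xb),
               fold_change = if (mean(xb) > 0) mean(xa) / mean(xb) else
                 NA_real_,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$pvalue) & out$pvalue < p_cut
  out
}
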