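# Pseudobulk RNA differential expression (DESeq2 negative-binomial engine,
# thresholds: adjusted p < 0.01 and |log2FC| > 1), cluster-specific and
# pan-CML gene-set logic, CLR normalization of ADT counts, and ADT
# differential testing with the Mann-Whitney U test and Bonferroni
# correction.

#' Randomly pseudobulk a group of cells into replicates
#'
#' Cells are randomly partitioned into `n_reps` near-equal subsets and
#' counts summed within each subset.
#'
#' @param counts Features x cells count matrix.
#' @param cells Cell names or indices forming the group.
#' @param n_reps Number of replicates (default 3).
#' @param seed Integer seed for the partition.
#' @return Features x replicates integer matrix.
#' @export
pseudobulk_replicates <- function(counts, cells = colnames(counts),
                                  n_reps = 3, seed = 1L) {
  sub <- counts[, cells, drop = FALSE]
  n <- ncol(sub)
  if (n < n_reps)
    stop("group has ", n, " cells; need at least n_reps = ", n_reps)
  set.seed(seed)
  assign <- sample(rep(seq_len(n_reps), length.out = n))
  out <- vapply(seq_len(n_reps), function(r)
    Matrix::rowSums(sub[, assign == r, drop = FALSE]), numeric(nrow(sub)))
  colnames(out) <- paste0("rep", seq_len(n_reps))
  out
}

#' Pseudobulk differential expression test
#'
#' Mitochondrial/ribosomal genes (by name prefix) and genes with total
#' count below `min_total` are excluded, then a negative-binomial Wald test
#' (DESeq2) compares the two replicate groups on size-factor-normalized
#' counts, with Benjamini-Hochberg adjustment. Significance requires
#' adjusted p < `padj_cut` and |log2FC| > `lfc_cut`. The fold change is
#' group A over group B.
#'
#' @param group_a,group_b Features x replicates pseudobulk count matrices.
#' @param padj_cut,lfc_cut Significance thresholds (defaults 0.01 and 1).
#' @param min_total Minimum total count across all replicates (default 10).
#' @param exclude_prefixes Gene-name prefixes to exclude (default
#'   mitochondrial `MT-` and ribosomal `RPL`/`RPS`).
#' @return data.frame with `gene`, `base_mean`, `log2fc`, `pvalue`, `padj`,
#'   `mean_a`, `mean_b`, `significant`.
#' @export
de_test <- function(group_a, group_b, padj_cut = 0.01, lfc_cut = 1,
                    min_total = 10,
                    exclude_prefixes = c("MT-", "RPL", "RPS")) {
  stopifnot(ncol(group_a) >= 2, ncol(group_b) >= 2,
            identical(rownames(group_a), rownames(group_b)))
  counts <- cbind(group_a, group_b)
  mode(counts) <- "integer"
  colnames(counts) <- c(paste0("a_", seq_len(ncol(group_a))),
                        paste0("b_", seq_len(ncol(group_b))))
  pat <- paste0("^(", paste(exclude_prefixes, collapse = "|"), ")")
  keep <- !grepl(pat, rownames(counts)) & rowSums(counts) >= min_total
  if (!any(keep)) {
    warning("all genes excluded")
    return(data.frame(gene = character(0), base_mean = numeric(0),
                      log2fc = numeric(0), pvalue = numeric(0),
                      padj = numeric(0), mean_a = numeric(0),
                      mean_b = numeric(0), significant = logical(0)))
  }
  counts <- counts[keep, , drop = FALSE]
  cond <- factor(rep(c("a", "b"), c(ncol(group_a), ncol(group_b))),
                 levels = c("b", "a"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = counts,
    colData = S4Vectors::DataFrame(condition = cond),
    design = ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE, fitType = "parametric")
  res <- DESeq2::results(dds, contrast = c("condition", "a", "b"),
                         independentFiltering = FALSE)
  norm <- DESeq2::counts(dds, normalized = TRUE)
  padj <- res$padj
  padj[is.na(padj)] <- 1
  pval <- res$pvalue
  pval[is.na(pval)] <- 1
  out <- data.frame(
    gene = rownames(counts),
    base_mean = res$baseMean,
    log2fc = res$log2FoldChange,
    pvalue = pval,
    padj = padj,
    mean_a = rowMeans(norm[, cond == "a", drop = FALSE]),
    mean_b = rowMeans(norm[, cond == "b", drop = FALSE]),
    stringsAsFactors = FALSE)
  out$significant <- out$padj < padj_cut & !is.na(out$log2fc) &
    abs(out$log2fc) > lfc_cut
  rownames(out) <- NULL
  out
}

#' Cluster-specific (unique) significant gene sets
#'
#' For each cluster's comparison, the significantly up- (and separately
#' down-) regulated genes that are not significant in any other cluster's
#' comparison.
#'
#' @param results Named list of [de_test()] result data.frames, one per
#'   cluster.
#' @return Named list with per-cluster `up` and `down` character vectors.
#' @export
cluster_specific_genes <- function(results) {
  if (length(results) < 2) stop("need results for at least 2 clusters")
  sig_up <- lapply(results, function(r) r$gene[r$significant & r$log2fc > 0])
  sig_dn <- lapply(results, function(r) r$gene[r$significant & r$log2fc < 0])
  sig_any <- lapply(results, function(r) r$gene[r$significant])
  lapply(stats::setNames(names(results), names(results)), function(cl) {
    others <- unique(unlist(sig_any[setdiff(names(results), cl)]))
    list(up = setdiff(sig_up[[cl]], others),
         down = setdiff(sig_dn[[cl]], others))
  })
}

#' Pan-CML signature gene sets
#'
#' Genes significantly up- (down-) regulated in every cluster's comparison.
#'
#' @param results Named list of [de_test()] results covering all required
#'   clusters.
#' @param required Cluster names that must be present (default: all names
#'   in `results`).
#' @return List with `up` and `down` character vectors.
#' @export
pan_signature <- function(results, required = names(results)) {
  missing <- setdiff(required, names(results))
  if (length(missing))
    stop("missing cluster results: ", paste(missing, collapse = ", "))
  results <- results[required]
  up <- Reduce(intersect, lapply(results, function(r)
    r$gene[r$significant & r$log2fc > 0]))
  down <- Reduce(intersect, lapply(results, function(r)
    r$gene[r$significant & r$log2fc < 0]))
  list(up = up, down = down)
}

#' Centered log-ratio (CLR) normalization of ADT counts
#'
#' Per cell, \eqn{CLR_i = \log(x_i + 1) - \frac{1}{m}\sum_j \log(x_j + 1)}
#' over that cell's antibodies (natural log; the pseudocount handles
#' zeros). Values sum to 0 within each cell.
#'
#' @param adt Antibodies x cells count matrix.
#' @return Dense antibodies x cells CLR matrix.
#' @export
clr_normalize <- function(adt) {
  if (nrow(adt) < 1) stop("need at least one antibody")
  lx <- log1p(as.matrix(adt))
  sweep(lx, 2, colMeans(lx))
}

# Mann-Whitney U test: exact p by enumeration of all labelings when the
# smaller group has <= `exact_max` observations (correct under ties),
# otherwise normal approximation with tie correction. Two-sided p is the
# probability of a U at least as far from its null mean as observed.
.mann_whitney <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (min(nx, ny) <= exact_max && (nx + ny) <= 24) {
    combs <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
  } else {
    n <- nx + ny
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs(u - mu) / sqrt(sigma2))
    p <- min(1, p)
  }
  list(statistic = u, p.value = p)
}

#' ADT differential test between two cell groups
#'
#' Per antibody, the log2 fold change is computed between the group means
#' of the CLR-derived linear expression values (`exp(CLR) * 1000`, see
#' [adt_to_scale()]); p-values come from a two-sided Mann-Whitney U test on
#' the per-cell CLR values and are Bonferroni-corrected over the tested
#' antibodies. Significance requires adjusted p < `p_cut` and |log2FC| >
#' `lfc_cut`.
#'
#' @param adt Antibodies x cells count matrix (both groups' cells).
#' @param group_pos,group_neg Cell names or indices of the two groups.
#' @param p_cut,lfc_cut Significance thresholds (defaults 0.05 and 1).
#' @return data.frame with `adt`, `log2fc`, `u`, `pvalue`, `padj`,
#'   `significant`.
#' @export
adt_differential <- function(adt, group_pos, group_neg, p_cut = 0.05,
                             lfc_cut = 1) {
  if (!length(group_pos) || !length(group_neg))
    stop("both groups must be non-empty")
  clr <- clr_normalize(adt)
  scaled <- adt_to_scale(clr)
  pos <- scaled[, group_pos, drop = FALSE]
  neg <- scaled[, group_neg, drop = FALSE]
  clr_pos <- clr[, group_pos, drop = FALSE]
  clr_neg <- clr[, group_neg, drop = FALSE]
  small <- ncol(pos) < 2 || ncol(neg) < 2
  if (small) warning("a group has a single cell; p reported as 1")
  res <- lapply(rownames(adt), function(ab) {
    lfc <- log2(mean(pos[ab, ]) / mean(neg[ab, ]))
    if (small) {
      list(statistic = NA_real_, p.value = 1, lfc = lfc)
    } else {
      mw <- .mann_whitney(clr_pos[ab, ], clr_neg[ab, ])
      list(statistic = mw$statistic, p.value = mw$p.value, lfc = lfc)
    }
  })
  m <- nrow(adt)
  out <- data.frame(
    adt = rownames(adt),
    log2fc = vapply(res, `[[`, 0, "lfc"),
    u = vapply(res, `[[`, 0, "statistic"),
    pvalue = vapply(res, `[[`, 0, "p.value"),
    stringsAsFactors = FALSE)
  out$padj <- pmin(1, m * out$pvalue)
  out$significant <- out$padj < p_cut & abs(out$log2fc) > lfc_cut
  out
}
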