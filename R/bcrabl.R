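# BCR::ABL1 status classification of primitive cells: merge primitive
# cells across patients (plus a normal bone marrow control), cluster at
# coarse resolution, score LSC/HSC signatures per cell, call each coarse
# cluster's status, and link statuses back to per-patient maps.

#' Merge primitive cells across patients with a control
#'
#' Concatenates the per-patient primitive-cell matrices and the control
#' matrix, keeping provenance (patient of origin, original cell id). HVGs
#' (default 500, min_cells 30, with a sex-linked exclusion list) and the
#' PCA are fitted on the CML cells only; control cells are projected into
#' that space. The graph uses the primitive-merge dialect (k = 11,
#' 20 PCs).
#'
#' @param patients Named list of features x cells count matrices (primitive
#'   cells per patient).
#' @param control Features x cells control (normal bone marrow) counts; may
#'   have zero columns.
#' @param n_hvgs,min_cells HVG dialect (defaults 500 / 30).
#' @param exclude_genes Sex-chromosome-linked gene names excluded from HVG
#'   selection.
#' @param k,n_pcs Graph dialect (defaults 11 / 20).
#' @return A `primitive_merge` list: `counts`, `provenance` (data.frame
#'   with `cell_id`, `patient`, `original_id`, `is_control`), `graph`.
#' @export
merge_primitive <- function(patients, control = NULL, n_hvgs = 500,
                            min_cells = 30, exclude_genes = character(0),
                            k = 11, n_pcs = 20) {
  keep <- vapply(patients, ncol, 0L) > 0
  if (any(!keep))
    warning("patients with 0 primitive cells skipped: ",
            paste(names(patients)[!keep], collapse = ", "))
  patients <- patients[keep]
  if (!length(patients)) stop("no patients with primitive cells")
  mats <- patients
  prov <- do.call(rbind, lapply(names(patients), function(p)
    data.frame(patient = p, original_id = colnames(patients[[p]]),
               is_control = FALSE, stringsAsFactors = FALSE)))
  if (!is.null(control) && ncol(control) > 0) {
    mats <- c(mats, list(control = control))
    prov <- rbind(prov, data.frame(patient = "control",
                                   original_id = colnames(control),
                                   is_control = TRUE,
                                   stringsAsFactors = FALSE))
  }
  counts <- do.call(cbind, mats)
  prov$cell_id <- paste(prov$patient, prov$original_id, sep = "|")
  colnames(counts) <- prov$cell_id
  cml <- !prov$is_control
  hvgs <- select_hvgs(counts[, cml, drop = FALSE], n_hvgs = n_hvgs,
                      min_cells = min_cells, exclude = exclude_genes)
  params <- graph_params(n_hvgs = length(hvgs), min_cells = min_cells,
                         n_pcs = n_pcs, k_neighbors = k,
                         umap_epochs = 500)
  graph <- build_graph(counts, hvgs, params, fit_cells = cml)
  structure(list(counts = counts, provenance = prov, graph = graph),
            class = "primitive_merge")
}

#' Coarse Leiden clustering of the primitive merge
#'
#' Runs [leiden_cluster()] at low resolution (default 0.1). On data with a
#' control population and two primitive sub-states this is expected to give
#' three coarse groups (control, BCR::ABL1+, BCR::ABL1-).
#'
#' @param merged A `primitive_merge` (or a `cell_graph`).
#' @param resolution Leiden resolution (default 0.1).
#' @param seed Integer seed.
#' @return Factor of coarse cluster labels.
#' @export
coarse_cluster <- function(merged, resolution = 0.1, seed = 1L) {
  graph <- if (inherits(merged, "primitive_merge")) merged$graph else merged
  if (nrow(graph$pcs) < 2) stop("cannot cluster fewer than 2 cells")
  leiden_cluster(graph, resolution = resolution, seed = seed)
}

#' Per-cell signature score
#'
#' Counts are library-size normalized (cell totals taken over the full
#' matrix) and log1p transformed; each present signature gene is z-scored
#' across cells; a cell's score is the mean z
#' over the variable signature genes. Genes constant across cells are
#' dropped (so the score is invariant to padding the signature with
#' constant genes; all-constant signatures score 0), and genes absent from
#' the matrix are dropped with a warning. Up- and down-gene lists are
#' scored as independent signatures.
#'
#' @param rna Features x cells count matrix.
#' @param genes Signature gene identifiers.
#' @return Named numeric vector of per-cell scores.
#' @export
score_signature <- function(rna, genes) {
  present <- intersect(genes, rownames(rna))
  if (!length(present)) stop("no signature genes present in the matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present),
            " signature genes absent; dropped")
  totals <- Matrix::colSums(rna)
  target <- stats::median(totals[totals > 0])
  sf <- ifelse(totals > 0, target / totals, 0)
  norm <- log1p(sweep(as.matrix(rna[present, , drop = FALSE]), 2, sf, "*"))
  sds <- matrixStats::rowSds(norm)
  variable <- sds > 0
  if (!any(variable))
    return(stats::setNames(rep(0, ncol(rna)), colnames(rna)))
  z <- .zscale_rows(norm[variable, , drop = FALSE],
                    rowMeans(norm)[variable], sds[variable])
  stats::setNames(colMeans(z), colnames(rna))
}

#' Call BCR::ABL1 status per coarse cluster
#'
#' The cluster holding the majority of the control cells is labeled
#' `"control"`. Each remaining cluster is labeled `"pos"` iff its mean LSC
#' score exceeds its mean HSC score and its LSC scores exceed the control
#' cluster's by a one-sided Wilcoxon rank-sum test at `alpha`; otherwise
#' `"neg"`. Without control cells the rank-sum comparison is against the
#' pooled other clusters (with a warning). Per-cell statuses are propagated
#' by cluster membership.
#'
#' @param clusters Per-cell coarse cluster labels.
#' @param lsc_score,hsc_score Per-cell signature scores (LSC = leukemic
#'   up-signature, HSC = normal-stem down-signature).
#' @param control_ids Cell ids (names of the score vectors) of control
#'   cells.
#' @param alpha Rank-sum significance level (default 0.05).
#' @return List with `cluster_status` (named by cluster) and `cell_status`
#'   (named by cell, values `pos`/`neg`/`control`).
#' @export
assign_status <- function(clusters, lsc_score, hsc_score, control_ids,
                          alpha = 0.05) {
  clusters <- stats::setNames(as.character(clusters), names(lsc_score))
  is_control <- names(lsc_score) %in% control_ids
  levs <- unique(clusters)
  control_cluster <- NULL
  if (any(is_control)) {
    ctl_share <- vapply(levs, function(cl)
      sum(is_control[clusters == cl]), 0)
    control_cluster <- levs[which.max(ctl_share)]
  } else {
    warning("no control cells: comparison is between CML clusters only")
  }
  cml_levs <- setdiff(levs, control_cluster)
  if (length(cml_levs) < 1) stop("need at least one non-control cluster")
  status <- stats::setNames(rep("neg", length(cml_levs)), cml_levs)
  for (cl in cml_levs) {
    in_cl <- clusters == cl
    baseline <- if (!is.null(control_cluster)) {
      lsc_score[clusters == control_cluster]
    } else lsc_score[clusters %in% setdiff(cml_levs, cl)]
    if (mean(lsc_score[in_cl]) <= mean(hsc_score[in_cl])) next
    if (!length(baseline)) next
    p <- stats::wilcox.test(lsc_score[in_cl], baseline,
                            alternative = "greater", exact = FALSE)$p.value
    if (!is.na(p) && p < alpha) status[cl] <- "pos"
  }
  cluster_status <- c(status,
                      stats::setNames(rep("control",
                                          length(control_cluster)),
                                      control_cluster))
  cell_status <- stats::setNames(cluster_status[clusters],
                                 names(clusters))
  list(cluster_status = cluster_status, cell_status = cell_status)
}

#' Link statuses back to per-patient annotated tables
#'
#' Joins the per-cell statuses (from the primitive merge) onto each
#' patient's merged cell table by cell id. Primitive cells carry their
#' status; other cells keep their transferred cluster label. Unmatched ids
#' are reported in the `unmatched` attribute, never silently dropped.
#'
#' @param patient_tables Named list of data.frames with columns `cell_id`
#'   and `label` (transferred cluster identity).
#' @param cell_status Named status vector (names are
#'   `"<patient>|<original_id>"` as produced by [merge_primitive()]).
#' @return Named list of annotated data.frames with a `status` column;
#'   each has an `unmatched` attribute listing status ids that found no
#'   cell in that patient's table.
#' @export
link_status <- function(patient_tables, cell_status) {
  out <- lapply(names(patient_tables), function(p) {
    tab <- patient_tables[[p]]
    ids <- paste(p, tab$cell_id, sep = "|")
    tab$status <- unname(cell_status[ids])
    tab$status[is.na(tab$status)] <- tab$label[is.na(tab$status)]
    mine <- grepl(paste0("^", p, "\\|"), names(cell_status))
    unmatched <- setdiff(names(cell_status)[mine], ids)
    attr(tab, "unmatched") <- unmatched
    tab
  })
  names(out) <- names(patient_tables)
  out
}
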