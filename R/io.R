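# Readers/writers for the 10x-convention Matrix Market layout and the
# pipeline driver tying the stages together.

#' Write count matrices in the 10x-convention MTX layout
#'
#' Writes `matrix.mtx`, `features.tsv` (id, name, type) and `barcodes.tsv`
#' to a directory. Multiple modalities are stacked with their feature type
#' tags (`Gene Expression`, `Antibody Capture`, `Multiplexing Capture`).
#'
#' @param mats Named list of features x cells matrices sharing the same
#'   cells; names in `rna`, `adt`, `hto` map to the standard type tags.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_counts <- function(mats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  type_map <- c(rna = "Gene Expression", adt = "Antibody Capture",
                hto = "Multiplexing Capture")
  barcodes <- colnames(mats[[1]])
  for (m in mats) stopifnot(identical(colnames(m), barcodes))
  stacked <- do.call(rbind, lapply(mats, .as_dgc))
  types <- unlist(lapply(names(mats), function(nm)
    rep(type_map[[nm]], nrow(mats[[nm]]))))
  feats <- unlist(lapply(mats, rownames))
  Matrix::writeMM(stacked, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(feats, feats, types),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a 10x-convention MTX directory
#'
#' Reads the matrix triplet plus `features.tsv` and `barcodes.tsv` and
#' splits the result by feature type tag into modalities.
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return Named list of sparse features x cells matrices (`rna`, `adt`,
#'   `hto`; only the modalities present).
#' @export
read_counts <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing file(s): ", paste(basename(missing), collapse = ", "))
  mat <- tryCatch(.as_dgc(Matrix::readMM(paths[1])), error = function(e)
    stop("malformed matrix triplet in ", paths[1], ": ",
         conditionMessage(e)))
  feats <- utils::read.table(paths[2], sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- readLines(paths[3])
  dup <- barcodes[duplicated(barcodes)]
  if (length(dup))
    stop("duplicated barcode(s): ", paste(unique(dup), collapse = ", "))
  if (nrow(feats) != nrow(mat) || length(barcodes) != ncol(mat))
    stop("feature/barcode tables do not match the matrix dimensions")
  rownames(mat) <- feats[[1]]
  colnames(mat) <- barcodes
  type <- if (ncol(feats) >= 3) feats[[3]] else
    rep("Gene Expression", nrow(feats))
  rev_map <- c("Gene Expression" = "rna", "Antibody Capture" = "adt",
               "Multiplexing Capture" = "hto")
  out <- lapply(split(seq_len(nrow(mat)), rev_map[type]),
                function(i) mat[i, , drop = FALSE])
  out[intersect(c("rna", "adt", "hto"), names(out))]
}

#' Run the analysis pipeline on one sample
#'
#' Executes QC filtering, hashtag demultiplexing, HTO/RNA doublet
#' exclusion, HVG/PCA/KNN/Leiden/UMAP, optional reference projection with
#' label transfer, and writes every stage's table to `outdir`
#' (`qc_demux.tsv`, `clusters.tsv`, `umap.tsv`, `labels.tsv`). Reruns with
#' the same config and seed reproduce all tables.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `counts_dir` (10x layout with at least RNA; HTO optional),
#'   `qc` (optional [qc_thresholds()] arguments), `graph` (optional
#'   [graph_params()] arguments), `reference` (optional: a
#'   `reference_model` or a list with `counts_dir` + `labels` TSV path),
#'   `seed`, `outdir`.
#' @return Named list of written file paths, invisibly; the computed
#'   objects are returned in the `results` attribute.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("counts_dir", "outdir"))
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  if (!dir.exists(config$counts_dir))
    stop("counts_dir does not exist: ", config$counts_dir)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  mods <- read_counts(config$counts_dir)
  if (is.null(mods$rna)) stop("no RNA modality in ", config$counts_dir)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  thr <- do.call(qc_thresholds, as.list(config$qc %||% list()))
  mask <- filter_cells(mods$rna, thr)
  rna <- mods$rna[, mask, drop = FALSE]

  demux_tab <- data.frame(cell_id = colnames(mods$rna), retained = mask)
  if (!is.null(mods$hto)) {
    dmx <- demultiplex(mods$hto[, mask, drop = FALSE],
                       fixed_thresholds = config$hto_thresholds)
    demux_tab$hashtag <- NA_character_
    demux_tab$hashtag[mask] <- dmx$labels
  }

  params <- do.call(graph_params, as.list(config$graph %||% list()))
  hvgs <- select_hvgs(rna, params$n_hvgs, params$min_cells)
  graph <- build_graph(rna, hvgs, params)
  clusters <- leiden_cluster(graph, params$leiden_resolution, seed = seed)

  if (!is.null(mods$hto)) {
    dbl <- exclude_hto_doublets(as.character(clusters),
                                mods$hto[, mask, drop = FALSE])
    demux_tab$doublet <- NA
    demux_tab$doublet[mask] <- dbl
  }
  emb <- umap_embed(graph, params, seed = seed)

  files <- list()
  write_tsv <- function(df, name) {
    p <- file.path(config$outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files$qc_demux <- write_tsv(demux_tab, "qc_demux.tsv")
  files$clusters <- write_tsv(
    data.frame(cell_id = colnames(rna), cluster = as.character(clusters)),
    "clusters.tsv")
  files$umap <- write_tsv(
    data.frame(cell_id = rownames(emb), emb), "umap.tsv")

  results <- list(mask = mask, clusters = clusters, umap = emb,
                  graph = graph)
  if (!is.null(config$reference)) {
    ref <- config$reference
    if (!inherits(ref, "reference_model")) {
      ref_mods <- read_counts(ref$counts_dir)
      lab_tab <- utils::read.table(ref$labels, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
      ref <- build_reference(ref_mods$rna,
                             lab_tab$cluster[match(colnames(ref_mods$rna),
                                                   lab_tab$cell_id)],
                             params)
    }
    proj <- map_cells(ref, rna,
                      n_neighbors = config$n_neighbors %||% 5)
    labels <- transfer_labels(proj,
                              threshold = config$label_threshold %||% 0.5)
    files$labels <- write_tsv(
      data.frame(cell_id = names(labels), label = labels), "labels.tsv")
    results$projection <- proj
    results$labels <- labels
  }
  attr(files, "results") <- results
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
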