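# Synthetic CITE-seq generator: an 11-cluster hematopoietic hierarchy with
# marker genes/ADTs, two primitive sub-states (BCR::ABL1+ LSC-like vs
# BCR::ABL1- HSC-like), hashtag counts with doublets, and bulk mixtures.
# Every generator is deterministic under its seed and returns ground truth.

#' Default hematopoietic cluster profiles
#'
#' Builds the generative profiles for an 11-cluster stem/progenitor
#' hierarchy (Primitive at the apex, then multipotent and lineage-committed
#' progenitors). Each cluster has a shared baseline of per-gene expected
#' counts with a disjoint set of marker genes boosted, and a 40-antibody
#' ADT panel with cluster markers boosted over background. The gene universe
#' contains mitochondrial (`MT-`) and ribosomal (`RPL`/`RPS`) names so QC
#' filters engage on generated data.
#'
#' @param n_genes Size of the gene universe (default 2000).
#' @param n_markers Marker genes boosted per cluster (default 15).
#' @param marker_boost Fold boost of marker-gene means (default 8).
#' @param adt_background Expected background ADT count (default 5).
#' @param adt_boost Fold boost of marker-ADT means (default 20).
#' @param seed Seed for the baseline mean draws.
#' @return Named list of cluster profiles; each profile is a list with
#'   `name`, `rna_means`, `adt_means`, `marker_genes`, `marker_adts`.
#' @export
default_profiles <- function(n_genes = 2000, n_markers = 15, marker_boost = 8,
                             adt_background = 5, adt_boost = 20, seed = 42L) {
  stopifnot(n_genes >= 200)
  clusters <- c("Primitive", "MPP-I", "MPP-II", "LMPP", "CMP", "GMP",
                "MEP", "MkP", "EryP", "CLP", "ProB")
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  genes[1:13] <- paste0("MT-G", 1:13)
  genes[14:53] <- c(paste0("RPL", 1:20), paste0("RPS", 1:20))
  adts <- c("CD34", "CD38", "CD90", "CD45RA", "CD49f", "CD10", "CD7",
            "CD117", "CD123", "CD33", "CD13", "CD14", "CD15", "CD11b",
            "CD36", "CD71", "CD41", "CD42b", "CD61", "CD19", "CD20",
            "CD22", "CD56", "CD16", "CD62L", "CD69", "CD44", "CD47",
            "CD52", "CD55", "CD64", "CD99", "CD133", "CD135", "HLA-DR",
            "CD161", "CD32", "CD26", "CD25", "CD35")
  withr_seed <- .child_seed(seed, 0L)
  set.seed(withr_seed)
  # Baseline expected counts sized for ~10k UMIs/cell over 2000 genes,
  # a realistic droplet CITE-seq depth.
  base <- (stats::rgamma(n_genes, shape = 2, rate = 2) + 0.05) * 5
  names(base) <- genes
  base[1:13] <- 15       # mitochondrial genes carry a visible UMI share
  base_adt <- rep(adt_background, length(adts))
  names(base_adt) <- adts

  # Disjoint marker blocks drawn from the non-MT, non-ribosomal tail;
  # CD26/CD25/CD35 are reserved for the leukemic/HSC sub-state contrast.
  free_genes <- genes[-(1:53)]
  adt_markers <- list(
    Primitive = c("CD34", "CD90", "CD49f"), `MPP-I` = c("CD34", "CD133"),
    `MPP-II` = c("CD34", "CD135"), LMPP = c("CD45RA", "CD7"),
    CMP = c("CD123", "CD33"), GMP = c("CD33", "CD13", "CD15"),
    MEP = c("CD36", "CD71"), MkP = c("CD41", "CD42b", "CD61"),
    EryP = c("CD71", "CD36"), CLP = c("CD10", "CD7"),
    ProB = c("CD19", "CD22", "CD10"))
  profiles <- vector("list", length(clusters))
  names(profiles) <- clusters
  for (i in seq_along(clusters)) {
    mg <- free_genes[((i - 1) * n_markers + 1):(i * n_markers)]
    rna <- base
    rna[mg] <- rna[mg] * marker_boost
    adt <- base_adt
    adt[adt_markers[[clusters[i]]]] <- adt_background * adt_boost
    profiles[[i]] <- list(name = clusters[i], rna_means = rna,
                          adt_means = adt, marker_genes = mg,
                          marker_adts = adt_markers[[clusters[i]]])
  }
  profiles
}

.check_profiles <- function(profiles) {
  if (!length(profiles)) stop("no cluster profiles supplied")
  nms <- vapply(profiles, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("cluster names must be unique")
  ref_genes <- names(profiles[[1]]$rna_means)
  ref_adts <- names(profiles[[1]]$adt_means)
  for (p in profiles) {
    if (!identical(names(p$rna_means), ref_genes) ||
        !identical(names(p$adt_means), ref_adts)) {
      stop("profile '", p$name,
           "' does not share the common feature universe")
    }
    if (!length(p$marker_genes)) stop("profile '", p$name, "' has no marker genes")
  }
  names(profiles) <- nms
  profiles
}

# Negative-binomial draws with mean mu and dispersion phi
# (variance mu + phi * mu^2); phi = 0 is the Poisson limit.
.rcounts <- function(mu, phi) {
  if (phi <= 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
}

# Sample a features x cells sparse count matrix given a per-cell matrix of
# expected values (features x cells).
.sample_counts <- function(mu, phi) {
  m <- matrix(.rcounts(as.numeric(mu), phi), nrow = nrow(mu),
              dimnames = dimnames(mu))
  .as_dgc(m)
}

#' Generate a labeled single-cell reference (RNA + ADT)
#'
#' Draws cells in equal shares from the given cluster profiles. RNA counts
#' follow a negative-binomial model with cluster-specific means, dispersion
#' `phi` (variance \eqn{m + \phi m^2}) and a per-cell log-normal library-size
#' factor; ADT counts use the same model on the background + boost ADT means.
#'
#' @param profiles Cluster profiles, as from [default_profiles()].
#' @param n_cells Total number of cells (at least one per profile).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param phi Negative-binomial dispersion (default 0.3; 0 gives Poisson).
#' @param libsize_sd Log-normal sd of the per-cell library-size factor
#'   (default 0.3; applied to both modalities).
#' @return List with `rna` and `adt` (sparse features x cells counts) and
#'   `truth`, a data.frame with one row per cell (`cell_id`, `cluster`,
#'   `status`, `hashtag`, `doublet`).
#' @export
generate_reference <- function(profiles, n_cells, seed = 1L, phi = 0.3,
                               libsize_sd = 0.3) {
  profiles <- .check_profiles(profiles)
  if (n_cells < length(profiles)) stop("n_cells must be >= number of profiles")
  set.seed(.child_seed(seed, 1L))
  cluster <- sample(rep(names(profiles), length.out = n_cells))
  cell_id <- sprintf("ref_%05d", seq_len(n_cells))
  lib <- exp(stats::rnorm(n_cells, 0, libsize_sd))
  rna_mu <- vapply(seq_len(n_cells),
                   function(i) profiles[[cluster[i]]]$rna_means * lib[i],
                   profiles[[1]]$rna_means)
  adt_mu <- vapply(seq_len(n_cells),
                   function(i) profiles[[cluster[i]]]$adt_means * lib[i],
                   profiles[[1]]$adt_means)
  colnames(rna_mu) <- cell_id
  colnames(adt_mu) <- cell_id
  truth <- data.frame(cell_id = cell_id, cluster = cluster, status = "n/a",
                      hashtag = NA_character_, doublet = FALSE,
                      stringsAsFactors = FALSE)
  list(rna = .sample_counts(rna_mu, phi), adt = .sample_counts(adt_mu, phi),
       truth = truth)
}

#' Default BCR::ABL1 signature gene sets
#'
#' Picks disjoint up- and down-regulated gene sets from the profiles' gene
#' universe (outside all cluster marker blocks), mirroring published
#' LSC-vs-HSC signatures whose up genes pass log2FC > 1 and down genes
#' log2FC < 0 in the source comparison. Only well-expressed genes are
#' eligible — a DE-derived signature consists of robustly detected genes.
#' The default sizes (50 up, 21 down) match the scale of signatures used
#' for status classification.
#'
#' @param profiles Cluster profiles sharing a gene universe.
#' @param n_up,n_down Number of up/down genes.
#' @return List with `name`, `up_genes`, `down_genes`.
#' @export
bcrabl_signature <- function(profiles, n_up = 50, n_down = 21) {
  free <- .expressed_free_genes(profiles)
  if (length(free) < n_up + n_down) stop("gene universe too small for signature")
  list(name = "BCRABL1_LSC", up_genes = free[seq_len(n_up)],
       down_genes = free[n_up + seq_len(n_down)])
}

# Free (non-marker, non-MT/ribosomal) genes with baseline expression at or
# above the free-gene median, in universe order.
.expressed_free_genes <- function(profiles) {
  profiles <- .check_profiles(profiles)
  means <- profiles[[1]]$rna_means
  genes <- names(means)
  used <- unique(c(grep("^MT-|^RP[LS]", genes, value = TRUE),
                   unlist(lapply(profiles, `[[`, "marker_genes"))))
  free <- setdiff(genes, used)
  free[means[free] >= stats::median(means[free])]
}

#' Default pan-CML gene set
#'
#' Genes shifted in every cell of a CML patient relative to normal bone
#' marrow, emulating a pan-cluster leukemia signature (sized like the
#' 50-up/21-down sets reported for CML across all clusters). Disjoint
#' from marker blocks and from [bcrabl_signature()] defaults.
#'
#' @inheritParams bcrabl_signature
#' @param n Number of genes (default 71, mirroring the size of a
#'   pan-cluster signature; silently clamped to the available pool).
#' @param offset Genes to skip after the signature block, so the sets stay
#'   disjoint from a default-sized [bcrabl_signature()].
#' @export
pan_cml_genes <- function(profiles, n = 71, offset = 71) {
  free <- .expressed_free_genes(profiles)
  avail <- length(free) - offset
  if (avail < 5)
    stop("gene universe too small for a pan-CML set after the signature block")
  free[offset + seq_len(min(n, avail))]
}

#' Patient design for the synthetic generator
#'
#' @param patient_id Text identifier.
#' @param composition Named vector of cluster proportions (sums to 1).
#' @param bcr_abl1_fraction Proportion of Primitive cells carrying the
#'   leukemic program, in `[0, 1]`.
#' @param signature_effect log2 fold change applied to signature up-genes in
#'   leukemic cells.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param pan_effect log2 fold change applied to the pan-CML gene set in all
#'   cells of the patient (default 2; set 0 to disable). A fusion-oncogene
#'   driven program shifts its targets severalfold.
#' @param pan_sd Per-cell log2 sd of the pan-CML effect (default 0.4),
#'   modeling cell-to-cell variability in leukemic program intensity; this
#'   is what makes the pan genes dispersed within a patient.
#' @return A `patient_design` list.
#' @export
patient_design <- function(patient_id, composition, bcr_abl1_fraction,
                           signature_effect = 1, n_cells = 1000, seed = 1L,
                           pan_effect = 2, pan_sd = 0.5) {
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop("composition proportions must be >= 0 and sum to 1")
  if (bcr_abl1_fraction < 0 || bcr_abl1_fraction > 1)
    stop("bcr_abl1_fraction must be in [0, 1]")
  structure(list(patient_id = patient_id, composition = composition,
                 bcr_abl1_fraction = bcr_abl1_fraction,
                 signature_effect = signature_effect, n_cells = n_cells,
                 seed = as.integer(seed), pan_effect = pan_effect,
                 pan_sd = pan_sd),
            class = "patient_design")
}

#' Generate a synthetic CML patient sample
#'
#' Cells are drawn per the design's cluster composition. Primitive cells are
#' split into BCR::ABL1+ (leukemic) and BCR::ABL1- sub-states by
#' `bcr_abl1_fraction`: leukemic cells have the signature's up-genes scaled
#' by `2^signature_effect`, its down-genes (the HSC program lost in
#' leukemic cells) by `2^-signature_effect`, and the leukemic marker ADTs
#' (CD26, CD25) boosted, while non-leukemic primitive cells have the HSC
#' marker ADT (CD35) boosted. All cells of the patient additionally carry
#' the pan-CML shift `2^pan_effect` on `pan_genes` (with per-cell
#' log-normal intensity variation `pan_sd`), emulating the leukemia-wide
#' expression program that separates patient cells from normal bone marrow.
#'
#' @param design A [patient_design()].
#' @param profiles Cluster profiles, as from [default_profiles()].
#' @param signature Signature list with `up_genes` (and optionally
#'   `down_genes`), as from [bcrabl_signature()].
#' @param pan_genes Pan-CML gene set (default [pan_cml_genes()]).
#' @param phi,libsize_sd As in [generate_reference()].
#' @param leukemic_adts,hsc_adts ADTs boosted in leukemic / non-leukemic
#'   primitive cells.
#' @param adt_state_boost Fold boost of the sub-state marker ADTs.
#' @return List with `rna`, `adt`, `truth`; `truth$status` is `"pos"`,
#'   `"neg"` (Primitive cells) or `"n/a"`.
#' @export
generate_patient <- function(design, profiles, signature,
                             pan_genes = pan_cml_genes(profiles),
                             phi = 0.3, libsize_sd = 0.3,
                             leukemic_adts = c("CD26", "CD25"),
                             hsc_adts = "CD35", adt_state_boost = 20) {
  stopifnot(inherits(design, "patient_design"))
  profiles <- .check_profiles(profiles)
  genes <- names(profiles[[1]]$rna_means)
  missing <- setdiff(c(signature$up_genes, signature$down_genes, pan_genes),
                     genes)
  if (length(missing))
    stop("signature/pan genes absent from the feature universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  comp <- design$composition[names(design$composition) %in% names(profiles)]
  if (length(comp) != length(design$composition))
    stop("composition names unknown to the profiles")
  set.seed(.child_seed(design$seed, 2L))
  n_cells <- design$n_cells
  cluster <- sample(names(comp), n_cells, replace = TRUE, prob = comp)
  status <- rep("n/a", n_cells)
  prim <- cluster == "Primitive"
  status[prim] <- ifelse(stats::rbinom(sum(prim), 1,
                                       design$bcr_abl1_fraction) == 1,
                         "pos", "neg")
  cell_id <- sprintf("%s_%05d", design$patient_id, seq_len(n_cells))
  lib <- exp(stats::rnorm(n_cells, 0, libsize_sd))
  rna_mu <- matrix(0, length(genes), n_cells, dimnames = list(genes, cell_id))
  adts <- names(profiles[[1]]$adt_means)
  adt_mu <- matrix(0, length(adts), n_cells, dimnames = list(adts, cell_id))
  pan_cell <- design$pan_effect +
    stats::rnorm(n_cells, 0, design$pan_sd %||% 0)
  for (i in seq_len(n_cells)) {
    rm <- profiles[[cluster[i]]]$rna_means
    am <- profiles[[cluster[i]]]$adt_means
    rm[pan_genes] <- rm[pan_genes] * 2^pan_cell[i]
    if (status[i] == "pos") {
      rm[signature$up_genes] <- rm[signature$up_genes] * 2^design$signature_effect
      if (length(signature$down_genes))
        rm[signature$down_genes] <-
          rm[signature$down_genes] * 2^-design$signature_effect
      am[leukemic_adts] <- am[leukemic_adts] * adt_state_boost
    } else if (status[i] == "neg") {
      am[hsc_adts] <- am[hsc_adts] * adt_state_boost
    }
    rna_mu[, i] <- rm * lib[i]
    adt_mu[, i] <- am * lib[i]
  }
  truth <- data.frame(cell_id = cell_id, cluster = cluster, status = status,
                      hashtag = NA_character_, doublet = FALSE,
                      stringsAsFactors = FALSE)
  list(rna = .sample_counts(rna_mu, phi), adt = .sample_counts(adt_mu, phi),
       truth = truth)
}

#' Generate hashtag-oligo (HTO) counts with doublets
#'
#' Every cell receives a hashtag identity uniformly at random; a
#' `doublet_rate` fraction of cells additionally carries a second, distinct
#' hashtag signal (doublets are modeled in HTO space only). Counts are
#' Poisson background plus Poisson signal on the assigned hashtag(s).
#'
#' @param truth Truth table from a generator (one row per cell).
#' @param n_hashtags Number of hashtags (>= 1).
#' @param doublet_rate Doublet proportion in `[0, 1)`.
#' @param seed Integer seed.
#' @param background_mean,signal_mean Poisson means of background and signal.
#' @return List with `hto` (hashtags x cells sparse counts) and the updated
#'   `truth` carrying `hashtag`, `hashtag2` and `doublet`.
#' @export
generate_hto <- function(truth, n_hashtags, doublet_rate = 0, seed = 1L,
                         background_mean = 2, signal_mean = 100) {
  if (n_hashtags < 1) stop("n_hashtags must be >= 1")
  if (doublet_rate < 0 || doublet_rate >= 1)
    stop("doublet_rate must be in [0, 1)")
  n <- nrow(truth)
  set.seed(.child_seed(seed, 3L))
  tags <- paste0("HTO_", seq_len(n_hashtags))
  primary <- sample(tags, n, replace = TRUE)
  doublet <- stats::rbinom(n, 1, doublet_rate) == 1 & n_hashtags > 1
  second <- rep(NA_character_, n)
  for (i in which(doublet)) second[i] <- sample(setdiff(tags, primary[i]), 1)
  counts <- matrix(stats::rpois(n_hashtags * n, background_mean),
                   nrow = n_hashtags, dimnames = list(tags, truth$cell_id))
  sig <- stats::rpois(n, signal_mean)
  counts[cbind(match(primary, tags), seq_len(n))] <-
    counts[cbind(match(primary, tags), seq_len(n))] + sig
  if (any(doublet)) {
    idx <- which(doublet)
    sig2 <- stats::rpois(length(idx), signal_mean)
    counts[cbind(match(second[idx], tags), idx)] <-
      counts[cbind(match(second[idx], tags), idx)] + sig2
  }
  truth$hashtag <- primary
  truth$hashtag2 <- second
  truth$doublet <- doublet
  list(hto = .as_dgc(counts), truth = truth)
}

#' Generate bulk expression mixtures of cluster profiles
#'
#' Each bulk sample is the fraction-weighted sum of the cluster mean RNA
#' profiles with multiplicative log-normal noise.
#'
#' @param profiles Cluster profiles.
#' @param fractions Samples x clusters matrix of mixing proportions (rows
#'   sum to 1, non-negative); column names must match profile names.
#' @param noise_sd sd of the log-normal noise (0 gives exact mixtures).
#' @param seed Integer seed.
#' @return List with `bulk` (genes x samples matrix) and `fractions` (the
#'   truth, as supplied).
#' @export
generate_bulk <- function(profiles, fractions, noise_sd = 0.1, seed = 1L) {
  profiles <- .check_profiles(profiles)
  fractions <- as.matrix(fractions)
  if (is.null(colnames(fractions)) ||
      !all(colnames(fractions) %in% names(profiles)))
    stop("fraction columns must name clusters present in the profiles")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("each sample's fractions must sum to 1")
  if (is.null(rownames(fractions)))
    rownames(fractions) <- sprintf("bulk_%03d", seq_len(nrow(fractions)))
  means <- vapply(profiles[colnames(fractions)], `[[`,
                  profiles[[1]]$rna_means, "rna_means")
  bulk <- means %*% t(fractions)  # genes x samples
  if (noise_sd > 0) {
    set.seed(.child_seed(seed, 4L))
    bulk <- bulk * exp(matrix(stats::rnorm(length(bulk), 0, noise_sd),
                              nrow(bulk)))
  }
  list(bulk = bulk, fractions = fractions)
}
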