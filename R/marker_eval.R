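# ADT scale transformation, threshold gating, capture fractions, and the
# LSC/HSC ratio from CD26/CD35 combination gates.

#' Transform CLR values to the scaled (linear) axis
#'
#' The cytometry-style export scale: `exp(CLR) * 1000` (antilog of the
#' centered log-ratio, times a scaling factor of 1000). Strictly positive;
#' a CLR of 0 maps to 1000.
#'
#' @param clr Antibodies x cells CLR matrix from [clr_normalize()].
#' @return Matrix of the same shape on the scaled axis.
#' @export
adt_to_scale <- function(clr) {
  if (any(!is.finite(clr))) stop("CLR values must be finite")
  exp(clr) * 1000
}

#' Define a surface-marker gate
#'
#' A conjunction of per-antibody terms on the scaled axis: a `+` term
#' requires the value to strictly exceed its threshold, a `-` term
#' requires it not to exceed it (so the four sign combinations over two
#' markers partition the cells).
#'
#' @param ... Named thresholds; the name is the antibody, a negative sign
#'   is written as a `"-"` suffix (e.g. `gate("CD26" = 700, "CD35-" = 700)`
#'   is CD26+CD35-).
#' @return A `gate_definition` data.frame with columns `adt`, `sign`,
#'   `threshold`.
#' @export
gate <- function(...) {
  args <- c(...)
  if (!length(args) || is.null(names(args))) stop("gate terms must be named")
  neg <- grepl("-$", names(args))
  adt <- sub("[+-]$", "", names(args))
  if (anyDuplicated(adt)) stop("antibodies must be distinct within a gate")
  if (any(args <= 0)) stop("gate thresholds must be > 0")
  structure(data.frame(adt = adt, sign = ifelse(neg, "-", "+"),
                       threshold = as.numeric(args),
                       stringsAsFactors = FALSE),
            class = c("gate_definition", "data.frame"))
}

#' Apply a gate to scaled ADT values
#'
#' @param scaled Antibodies x cells matrix from [adt_to_scale()].
#' @param gate_def A [gate()] definition.
#' @return Named logical mask over cells.
#' @export
apply_gate <- function(scaled, gate_def) {
  missing <- setdiff(gate_def$adt, rownames(scaled))
  if (length(missing))
    stop("gate references antibodies absent from the table: ",
         paste(missing, collapse = ", "))
  mask <- rep(TRUE, ncol(scaled))
  for (i in seq_len(nrow(gate_def))) {
    v <- scaled[gate_def$adt[i], ]
    mask <- mask & if (gate_def$sign[i] == "+")
      v > gate_def$threshold[i] else v <= gate_def$threshold[i]
  }
  names(mask) <- colnames(scaled)
  mask
}

#' Capture fraction of a population by a gate
#'
#' The fraction of a defined cell population falling inside the gate,
#' `|mask ∩ population| / |population|`.
#'
#' @param mask Logical gate mask (named by cell) or character cell ids.
#' @param population Cell ids of the population.
#' @return List with `fraction` (`NA` for an empty population),
#'   `n_captured`, `n_population`.
#' @export
capture_fraction <- function(mask, population) {
  gated <- if (is.logical(mask)) names(mask)[mask] else mask
  n_pop <- length(population)
  if (n_pop == 0)
    return(list(fraction = NA_real_, n_captured = 0L, n_population = 0L))
  n_cap <- length(intersect(gated, population))
  list(fraction = n_cap / n_pop, n_captured = n_cap, n_population = n_pop)
}

#' LSC/HSC ratio from CD26/CD35 combination gates
#'
#' Counts CD26+CD35- (LSC-like) and CD26-CD35+ (HSC-like) cells within a
#' compartment and reports their ratio (missing when the denominator is 0).
#'
#' @param scaled Antibodies x cells matrix from [adt_to_scale()].
#' @param cd26_threshold,cd35_threshold Gate positions on the scaled axis.
#' @param compartment Cell ids of the compartment (default: all cells).
#' @param cd26,cd35 Antibody names (defaults `"CD26"`, `"CD35"`).
#' @return List with `n_lsc`, `n_hsc`, `ratio`.
#' @export
lsc_hsc_ratio <- function(scaled, cd26_threshold, cd35_threshold,
                          compartment = colnames(scaled),
                          cd26 = "CD26", cd35 = "CD35") {
  if (!length(compartment)) stop("compartment must be non-empty")
  sub <- scaled[, compartment, drop = FALSE]
  lsc <- apply_gate(sub, gate(stats::setNames(c(cd26_threshold,
                                                cd35_threshold),
                                              c(cd26, paste0(cd35, "-")))))
  hsc <- apply_gate(sub, gate(stats::setNames(c(cd26_threshold,
                                                cd35_threshold),
                                              c(paste0(cd26, "-"), cd35))))
  n_lsc <- sum(lsc); n_hsc <- sum(hsc)
  list(n_lsc = n_lsc, n_hsc = n_hsc,
       ratio = if (n_hsc > 0) n_lsc / n_hsc else NA_real_)
}
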