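# CNV signal inference from genome-ordered expression and the
# malignant-cell classifier: per-cell mean-square CNV score, reference
# vector from the top-5% scoring cells, Pearson r > 0.3 call.

#' Infer smoothed per-cell CNV signals
#'
#' A minimal moving-average CNV estimator over genome-ordered expression:
#' per gene the reference-cell mean is subtracted from the log-normalized
#' values, residuals are clipped to `[-clip, clip]`, smoothed along genome
#' order with a centered moving average of width `window` within each
#' chromosome (the window shrinks at chromosome edges and on chromosomes
#' shorter than the window), each cell's median smoothed value is
#' subtracted (recentering against cell-wide shifts), and finally the
#' reference cells' mean smoothed signal is subtracted gene-wise
#' (re-standardization) so that reference-like cells sit near 0.
#'
#' Genes lacking coordinates are dropped with a warning. Reference cells
#' may overlap the query set (reference and query are pooled in the
#' underlying study design).
#'
#' @param nm A [norm_matrix()] holding query and reference cells.
#' @param reference_cells Logical or integer index of reference cells
#'   within `nm` (non-empty).
#' @param window Odd moving-average width in genes (default 101).
#' @param clip Residual clip bound (default 3).
#' @return A `cnv_profile`: list with `signal` (cell x gene matrix,
#'   genome-ordered genes), `genes`, `cells`, `reference_cells`, `params`.
#' @export
infer_cnv_profile <- function(nm, reference_cells, window = 101, clip = 3) {
  stopifnot(window >= 3, window %% 2 == 1, clip > 0)
  if (is.logical(reference_cells)) reference_cells <- which(reference_cells)
  if (!length(reference_cells)) stop("reference_cells must be non-empty")
  genes <- nm$genes
  has_coord <- !is.na(genes$chromosome) & !is.na(genes$start)
  if (!all(has_coord)) {
    warning(sum(!has_coord), " gene(s) lacking coordinates dropped")
  }
  # the mitochondrial contig carries no copy-number information and its
  # expression varies with per-cell mitochondrial content; excluded
  has_coord <- has_coord &
    !toupper(sub("^chr", "", genes$chromosome, ignore.case = TRUE)) %in%
      c("M", "MT")
  ord <- which(has_coord)[genome_order(genes[has_coord, , drop = FALSE])]
  genes <- genes[ord, , drop = FALSE]
  x <- as.matrix(nm$values[ord, , drop = FALSE])   # gene x cell, genome order
  ref_mean <- rowMeans(x[, reference_cells, drop = FALSE])
  resid <- pmin(pmax(x - ref_mean, -clip), clip)
  chroms <- genes$chromosome
  smoothed <- matrix(0, nrow(resid), ncol(resid))
  for (ch in unique(chroms)) {
    rows <- which(chroms == ch)
    w <- min(window, length(rows))
    if (w %% 2 == 0) w <- w - 1L
    smoothed[rows, ] <- running_mean(resid[rows, , drop = FALSE], max(w, 1L))
  }
  med <- apply(smoothed, 2L, stats::median)
  smoothed <- sweep(smoothed, 2L, med, "-")
  ref_smooth <- rowMeans(smoothed[, reference_cells, drop = FALSE])
  signal <- t(smoothed - ref_smooth)               # cell x gene
  rownames(signal) <- colnames(nm$values)
  colnames(signal) <- genes$gene_id
  structure(list(signal = signal, genes = genes, cells = nm$cells,
                 reference_cells = reference_cells,
                 params = list(window = window, clip = clip)),
            class = "cnv_profile")
}

#' Per-cell CNV score
#'
#' The mean square of the re-standardized CNV signals:
#' `score(c) = mean_g signal(c, g)^2`.
#'
#' @param profile A `cnv_profile`.
#' @return Named numeric vector, one score per cell.
#' @export
cnv_cell_score <- function(profile) {
  rowMeans(profile$signal^2)
}

#' CNV reference vector from the top-scoring cells
#'
#' Selects the `ceiling(top_frac * n_cells)` cells with the highest CNV
#' score (at least 1; ties broken by cell order) and averages their signed
#' signal gene-wise. Averaging the signed signal rather than the squared
#' score preserves the amplification/deletion sign that the downstream
#' correlation needs.
#'
#' @param profile A `cnv_profile`.
#' @param top_frac Fraction of cells to average (default 0.05).
#' @return Named numeric vector over genes, with attribute `cells` giving
#'   the selected cell indices.
#' @export
build_reference_vector <- function(profile, top_frac = 0.05) {
  stopifnot(top_frac > 0, top_frac < 1)
  n <- nrow(profile$signal)
  if (n == 0) stop("no cells in profile")
  scores <- cnv_cell_score(profile)
  k <- max(1L, ceiling(top_frac * n))
  sel <- order(-scores, seq_len(n))[seq_len(k)]
  v <- colMeans(profile$signal[sel, , drop = FALSE])
  attr(v, "cells") <- sel
  v
}

#' Classify malignant cells by correlation with the reference vector
#'
#' A cell is called malignant when the Pearson correlation between its CNV
#' signal and the reference vector is strictly above `r_threshold`. Cells
#' with a zero-variance signal have undefined correlation and are called
#' non-malignant with a flag.
#'
#' @param profile A `cnv_profile`.
#' @param reference_vector Per-gene reference (from
#'   [build_reference_vector()]); must have nonzero variance.
#' @param r_threshold Strict correlation threshold (default 0.3).
#' @return Data frame: `r`, `malignant`, `undefined_r`, one row per cell.
#' @export
classify_malignant <- function(profile, reference_vector, r_threshold = 0.3) {
  if (stats::sd(reference_vector) == 0) {
    stop("reference vector has zero variance")
  }
  sds <- apply(profile$signal, 1L, stats::sd)
  r <- rep(NA_real_, nrow(profile$signal))
  ok <- sds > 0
  if (any(ok)) {
    r[ok] <- as.vector(stats::cor(t(profile$signal[ok, , drop = FALSE]),
                                  as.vector(reference_vector)))
  }
  data.frame(r = r, malignant = !is.na(r) & r > r_threshold,
             undefined_r = !ok, stringsAsFactors = FALSE)
}

#' Per-patient malignant-cell calling
#'
#' Pools the epithelial-compartment cells of a patient's GG and solid
#' samples as the query, uses the configured reference populations (normal
#' epithelial cells from normal-lung samples, T cells, endothelial cells
#' and fibroblasts) as the CNV baseline, infers the CNV profile, builds the
#' top-`top_frac` reference vector and classifies every query cell.
#'
#' @param nm A multi-sample [norm_matrix()] whose `cells` table carries
#'   `patient_id`, `group` and `label`.
#' @param query_labels Labels forming the epithelial query compartment
#'   (default `c("Epithelial", "Malignant")`; on real data all epithelial
#'   cells share one label).
#' @param reference_labels Labels used as the CNV baseline.
#' @param window,clip,top_frac,r_threshold See the stage functions.
#' @return Data frame with one row per query cell: sample, barcode, CNV
#'   score, correlation `r`, `malignant` call.
#' @export
call_malignant_cells <- function(nm,
                                 query_labels = c("Epithelial", "Malignant"),
                                 reference_labels = c("T", "Endothelial",
                                                      "Fibroblast"),
                                 window = 101, clip = 3, top_frac = 0.05,
                                 r_threshold = 0.3) {
  stopifnot(!is.null(nm$cells$label))
  out <- list()
  for (pat in unique(nm$cells$patient_id)) {
    in_pat <- nm$cells$patient_id == pat
    is_query <- in_pat & nm$cells$group %in% c("GG", "solid") &
      nm$cells$label %in% query_labels
    is_ref <- in_pat & (nm$cells$label %in% reference_labels |
                          (nm$cells$group == "nLung" &
                             nm$cells$label %in% query_labels))
    if (!any(is_query) || !any(is_ref)) next
    sub <- subset_cells(nm, is_query | is_ref)
    prof <- infer_cnv_profile(sub, reference_cells = which(is_ref[is_query | is_ref]),
                              window = window, clip = clip)
    q_in_sub <- which(is_query[is_query | is_ref])
    q_prof <- prof
    q_prof$signal <- prof$signal[q_in_sub, , drop = FALSE]
    q_prof$cells <- prof$cells[q_in_sub, , drop = FALSE]
    ref_vec <- build_reference_vector(q_prof, top_frac)
    call <- classify_malignant(q_prof, ref_vec, r_threshold)
    out[[pat]] <- cbind(q_prof$cells[, c("sample_id", "barcode", "patient_id",
                                         "group")],
                        score = cnv_cell_score(q_prof), call)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
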