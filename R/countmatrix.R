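#' Sparse UMI count matrix for one sample
#'
#' The central container of the pipeline: a sparse gene x cell matrix of
#' non-negative integer UMI counts together with gene annotation (id, symbol,
#' chromosome, start coordinate), cell barcodes, and sample-level metadata
#' (sample id, patient id, clinical group). Optionally carries per-cell
#' labels (cell types).
#'
#' @param counts Gene x cell matrix coercible to `Matrix::dgCMatrix`;
#'   non-negative integers.
#' @param genes Data frame with columns `gene_id`, `symbol`, `chromosome`,
#'   `start` (0-based position), one row per matrix row.
#' @param barcodes Character vector of cell barcodes, unique within the
#'   sample, one per matrix column.
#' @param sample_id,patient_id Character scalars.
#' @param group Clinical group, one of `"nLung"`, `"GG"`, `"solid"`.
#' @param labels Optional character vector of per-cell type labels.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, genes, barcodes, sample_id, patient_id,
                         group, labels = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("gene_id", "symbol", "chromosome", "start")
  if (!all(required %in% names(genes))) {
    stop("genes must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(genes) != nrow(counts)) {
    stop("genes has ", nrow(genes), " rows but counts has ", nrow(counts))
  }
  barcodes <- as.character(barcodes)
  if (length(barcodes) != ncol(counts)) {
    stop("barcodes length ", length(barcodes), " != ", ncol(counts), " cells")
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcodes within sample ", sample_id)
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x)))) {
    stop("counts must be non-negative integers")
  }
  group <- match.arg(group, c("nLung", "GG", "solid"))
  if (!is.null(labels) && length(labels) != ncol(counts)) {
    stop("labels length must equal cell count")
  }
  dimnames(counts) <- list(genes$gene_id, barcodes)
  structure(list(counts = counts, genes = genes, barcodes = barcodes,
                 sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 group = group, labels = labels),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells | sample=%s patient=%s group=%s\n",
              nrow(x$counts), ncol(x$counts), x$sample_id, x$patient_id, x$group))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @method all.equal count_matrix
#' @export
all.equal.count_matrix <- function(target, current, ...) {
  msgs <- character()
  if (!isTRUE(all.equal(as.matrix(target$counts), as.matrix(current$counts),
                        check.attributes = FALSE))) {
    msgs <- c(msgs, "counts differ")
  }
  for (f in c("barcodes", "sample_id", "patient_id", "group")) {
    if (!identical(target[[f]], current[[f]])) msgs <- c(msgs, paste(f, "differs"))
  }
  g1 <- target$genes[c("gene_id", "symbol", "chromosome", "start")]
  g2 <- current$genes[c("gene_id", "symbol", "chromosome", "start")]
  rownames(g1) <- rownames(g2) <- NULL
  g1$start <- as.numeric(g1$start); g2$start <- as.numeric(g2$start)
  if (!isTRUE(all.equal(g1, g2, check.attributes = FALSE))) {
    msgs <- c(msgs, "gene annotation differs")
  }
  if (length(msgs)) msgs else TRUE
}

#' Log-normalized expression matrix
#'
#' Holds `ln(count / cell_total * scale_factor + 1)` values for one or more
#' samples, plus a per-cell metadata table and the QC provenance that
#' produced it. Constructed by [lognormalize()] or [merge_norm()].
#'
#' @param values Sparse gene x cell matrix of normalized values.
#' @param genes Gene annotation data frame (as in [count_matrix()]).
#' @param cells Data frame with one row per cell: `barcode`, `sample_id`,
#'   `patient_id`, `group`, optional `label`.
#' @param scale_factor Scale factor used in the transform.
#' @param qc_summary Optional data frame recording cells/genes removed per rule.
#' @return An object of class `norm_matrix`.
#' @export
norm_matrix <- function(values, genes, cells, scale_factor = 10000,
                        qc_summary = NULL) {
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  stopifnot(nrow(genes) == nrow(values), nrow(cells) == ncol(values))
  key <- paste(cells$sample_id, cells$barcode)
  if (anyDuplicated(key)) stop("duplicate (sample, barcode) pairs")
  dimnames(values) <- list(genes$gene_id, key)
  structure(list(values = values, genes = as.data.frame(genes), cells = cells,
                 scale_factor = scale_factor, qc_summary = qc_summary),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d genes x %d cells | %d sample(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$cells$sample_id))))
  invisible(x)
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

#' Merge normalized samples sharing a gene panel
#'
#' Column-binds per-sample normalized matrices into one multi-sample
#' `norm_matrix`. All samples must share an identical gene annotation.
#'
#' @param nm_list List of `norm_matrix` objects.
#' @return A single `norm_matrix`.
#' @export
merge_norm <- function(nm_list) {
  stopifnot(length(nm_list) >= 1L)
  g0 <- nm_list[[1L]]$genes$gene_id
  for (nm in nm_list) {
    if (!identical(nm$genes$gene_id, g0)) {
      stop("samples do not share a gene panel; merge requires identical genes")
    }
  }
  values <- do.call(cbind, lapply(nm_list, function(nm) nm$values))
  cells <- do.call(rbind, lapply(nm_list, function(nm) nm$cells))
  rownames(cells) <- NULL
  norm_matrix(values, nm_list[[1L]]$genes, cells,
              scale_factor = nm_list[[1L]]$scale_factor)
}

#' Subset a norm_matrix by cells
#'
#' @param nm A `norm_matrix`.
#' @param idx Logical or integer index over cells.
#' @return The subsetted `norm_matrix`.
#' @export
subset_cells <- function(nm, idx) {
  norm_matrix(nm$values[, idx, drop = FALSE], nm$genes,
              nm$cells[idx, , drop = FALSE], nm$scale_factor, nm$qc_summary)
}
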