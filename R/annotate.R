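# Plumbing for label intake when no cell-type labels are supplied:
# PCA + seeded k-means clusters, annotated by marker-set mean expression.
# This is deliberately plain machinery, not a graph-clustering
# reimplementation; supplied labels always take precedence in the pipeline.

#' Cluster cells by PCA + k-means (fallback labeling)
#'
#' Scales the chosen genes, takes the top principal components and runs
#' k-means with a seeded deterministic start. Intended only as a fallback
#' when no labels are supplied.
#'
#' @param nm A [norm_matrix()].
#' @param genes_use Gene ids to use (default: all).
#' @param n_pcs Principal components (default 30, capped by dimensions).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return Integer cluster assignment per cell.
#' @export
cluster_cells <- function(nm, genes_use = NULL, n_pcs = 30, k = 8, seed = 1L) {
  x <- nm$values
  if (!is.null(genes_use)) {
    x <- x[nm$genes$gene_id %in% genes_use, , drop = FALSE]
  }
  xm <- t(as.matrix(x))
  keep <- apply(xm, 2L, stats::sd) > 0
  xm <- scale(xm[, keep, drop = FALSE])
  n_pcs <- min(n_pcs, dim(xm) - 1L)
  pc <- stats::prcomp(xm, rank. = n_pcs)$x
  with_preserved_rng(seed,
    stats::kmeans(pc, centers = k, nstart = 5, iter.max = 50)$cluster)
}

#' Annotate clusters by marker expression
#'
#' Assigns each cluster the cell type whose marker set has the highest mean
#' normalized expression across the cluster's cells.
#'
#' @param nm A [norm_matrix()].
#' @param clusters Integer cluster per cell.
#' @param marker_table Named list: type -> marker gene symbols.
#' @return Character label per cell.
#' @export
annotate_clusters <- function(nm, clusters, marker_table) {
  stopifnot(length(marker_table) >= 1)
  sym <- nm$genes$symbol
  type_means <- sapply(marker_table, function(markers) {
    rows <- match(intersect(markers, sym), sym)
    if (!length(rows)) return(rep(-Inf, ncol(nm$values)))
    Matrix::colMeans(nm$values[rows, , drop = FALSE])
  })
  labels <- character(length(clusters))
  for (cl in unique(clusters)) {
    idx <- clusters == cl
    labels[idx] <- names(marker_table)[
      which.max(colMeans(type_means[idx, , drop = FALSE]))]
  }
  labels
}
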