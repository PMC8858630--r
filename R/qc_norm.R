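#' Identify mitochondrial genes by symbol
#'
#' Community convention: gene symbols with case-insensitive prefix "MT-".
#'
#' @param symbols Character vector of gene symbols.
#' @return Logical vector.
#' @export
is_mito_gene <- function(symbols) {
  grepl("^MT-", symbols, ignore.case = TRUE)
}

#' Per-cell QC metrics
#'
#' @param m A [count_matrix()].
#' @return Data frame with `barcode`, `n_genes` (genes with nonzero count),
#'   `n_umis`, `mito_frac`.
#' @export
cell_qc_metrics <- function(m) {
  totals <- Matrix::colSums(m$counts)
  n_genes <- Matrix::colSums(m$counts > 0)
  mito <- is_mito_gene(m$genes$symbol)
  mito_umis <- if (any(mito)) Matrix::colSums(m$counts[mito, , drop = FALSE]) else 0
  mito_frac <- ifelse(totals > 0, mito_umis / totals, 0)
  data.frame(barcode = m$barcodes, n_genes = as.integer(n_genes),
             n_umis = totals, mito_frac = mito_frac,
             stringsAsFactors = FALSE)
}

#' Remove low-quality cells
#'
#' Retains exactly the cells with `min_genes <= detected genes <= max_genes`,
#' mitochondrial UMI fraction `<= max_mito_frac`, and total UMIs
#' `<= max_umis`. The removal rules are exclusive ("fewer than 200", "more
#' than 6000/15%/60,000"), so boundary cells are retained. A QC summary
#' attached to the result records how many cells each rule removed (a cell
#' failing several rules is counted under each).
#'
#' @param m A [count_matrix()].
#' @param min_genes,max_genes Detected-gene retention bounds (default 200, 6000).
#' @param max_mito_frac Maximum mitochondrial UMI fraction (default 0.15).
#' @param max_umis Maximum total UMIs (default 60000).
#' @return A `count_matrix` of the retained cells, with attribute
#'   `qc_summary` (data frame: rule, cells_removed).
#' @export
filter_cells <- function(m, min_genes = 200, max_genes = 6000,
                         max_mito_frac = 0.15, max_umis = 60000) {
  qc <- cell_qc_metrics(m)
  low  <- qc$n_genes < min_genes
  high <- qc$n_genes > max_genes
  mito <- qc$mito_frac > max_mito_frac
  umi  <- qc$n_umis > max_umis
  keep <- !(low | high | mito | umi)
  out <- count_matrix(m$counts[, keep, drop = FALSE], m$genes,
                      m$barcodes[keep], m$sample_id, m$patient_id, m$group,
                      if (!is.null(m$labels)) m$labels[keep])
  attr(out, "qc_summary") <- data.frame(
    rule = c("low_genes", "high_genes", "high_mito", "high_umi"),
    cells_removed = c(sum(low), sum(high), sum(mito), sum(umi)),
    stringsAsFactors = FALSE)
  out
}

#' Remove genes detected in too few cells
#'
#' Keeps genes with a nonzero count in at least `min_cells` cells
#' (boundary inclusive: a gene seen in exactly `min_cells` cells stays).
#'
#' @param m A [count_matrix()].
#' @param min_cells Minimum number of cells (default 5).
#' @return A `count_matrix` restricted to the retained genes.
#' @export
filter_genes <- function(m, min_cells = 5) {
  stopifnot(min_cells >= 0)
  keep <- Matrix::rowSums(m$counts > 0) >= min_cells
  count_matrix(m$counts[keep, , drop = FALSE],
               m$genes[keep, , drop = FALSE], m$barcodes,
               m$sample_id, m$patient_id, m$group, m$labels)
}

#' Log-normalize a count matrix
#'
#' Each cell's counts are divided by its total, multiplied by
#' `scale_factor`, and transformed as `ln(x + 1)`; zero counts stay zero so
#' sparsity is preserved. For every cell with a positive total the values
#' satisfy `sum(exp(value) - 1) == scale_factor` exactly (up to floating
#' point). Cells with total 0 get all-zero values with a warning.
#'
#' @param m A [count_matrix()].
#' @param scale_factor Positive scale factor (default 10000).
#' @param qc_summary Optional provenance to attach.
#' @return A [norm_matrix()].
#' @export
lognormalize <- function(m, scale_factor = 10000, qc_summary = NULL) {
  stopifnot(scale_factor > 0)
  x <- m$counts
  totals <- Matrix::colSums(x)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total counts; values set to 0")
  }
  v <- x
  if (length(v@x)) {
    cell_of_entry <- rep.int(seq_len(ncol(x)), diff(x@p))
    denom <- totals[cell_of_entry]
    vals <- ifelse(denom > 0, log1p(x@x / denom * scale_factor), 0)
    v@x <- vals
  }
  cells <- data.frame(barcode = m$barcodes, sample_id = m$sample_id,
                      patient_id = m$patient_id, group = m$group,
                      stringsAsFactors = FALSE)
  if (!is.null(m$labels)) cells$label <- m$labels
  norm_matrix(Matrix::drop0(v), m$genes, cells, scale_factor, qc_summary)
}

#' Select highly variable genes (vst-style)
#'
#' Ranks genes by standardized variance: a smooth mean-variance trend is fit
#' on the log10 scale (ridge-regularized quadratic in log10 mean — a
#' deterministic approximation of the local regression used by the "vst"
#' selection method), each gene's raw counts are z-scored with the
#' trend-predicted standard deviation, z-values are clipped at
#' `sqrt(n_cells)`, and genes are ranked by the variance of the clipped z.
#' Constant genes have standardized variance 0 and are never selected ahead
#' of a variable gene.
#'
#' @param m A [count_matrix()] (selection operates on raw counts).
#' @param n Number of genes to select (default 2000).
#' @return Character vector of `min(n, eligible)` gene ids, ranked.
#' @export
select_variable_genes <- function(m, n = 2000) {
  stopifnot(n >= 1)
  sv <- standardized_variance(m$counts)
  ranked <- m$genes$gene_id[order(-sv, m$genes$gene_id)]
  eligible <- sum(sv > 0)
  ranked[seq_len(min(n, max(eligible, 0)))]
}

#' Standardized variance of each gene (vst statistic)
#'
#' @param counts Sparse gene x cell count matrix.
#' @return Numeric vector, one standardized variance per gene.
#' @export
standardized_variance <- function(counts, clip = NULL) {
  nc <- ncol(counts)
  mu <- Matrix::rowMeans(counts)
  ex2 <- Matrix::rowMeans(counts^2)
  v <- (ex2 - mu^2) * nc / max(nc - 1, 1)
  sv <- numeric(nrow(counts))
  ok <- mu > 0 & v > 0
  if (length(unique(mu[ok])) < 3) {
    # trend undefined; fall back to raw variance ranking
    message("fewer than 3 distinct gene means; using raw variance")
    return(v)
  }
  lm_ <- log10(mu[ok]); lv_ <- log10(v[ok])
  X <- cbind(1, lm_, lm_^2)
  ridge <- diag(c(0, 1e-8, 1e-8))
  beta <- solve(crossprod(X) + ridge, crossprod(X, lv_))
  pred_sd <- sqrt(10^(as.vector(X %*% beta)))
  clip <- clip %||% sqrt(nc)
  # variance of clipped z-scores, computed from the sparse structure:
  # zeros contribute the clipped value of (0 - mu)/sd, (nc - nnz) times.
  tc <- methods::as(methods::as(Matrix::t(counts[ok, , drop = FALSE]),
                                "generalMatrix"), "CsparseMatrix")
  nnz <- diff(tc@p)
  gene_of_entry <- rep.int(seq_len(ncol(tc)), nnz)
  mu_ok <- mu[ok]
  z <- (tc@x - mu_ok[gene_of_entry]) / pred_sd[gene_of_entry]
  z <- pmin(pmax(z, -clip), clip)
  z0 <- pmin(pmax(-mu_ok / pred_sd, -clip), clip)
  s1 <- unname(tapply(z, factor(gene_of_entry, levels = seq_along(mu_ok)), sum,
                      default = 0)) + (nc - nnz) * z0
  s2 <- unname(tapply(z^2, factor(gene_of_entry, levels = seq_along(mu_ok)), sum,
                      default = 0)) + (nc - nnz) * z0^2
  sv[ok] <- (s2 - s1^2 / nc) / max(nc - 1, 1)
  sv
}

#' Flag doublets by marker co-expression
#'
#' A cell is flagged as a doublet when it expresses canonical markers of two
#' or more distinct cell types. A marker set counts as "expressed" in a cell
#' when more than `min_fraction` of its genes have a nonzero normalized
#' value (the quantitative rule is a package choice; the qualitative
#' criterion is marker co-expression).
#'
#' @param nm A [norm_matrix()].
#' @param marker_table Named list: cell type -> character vector of marker
#'   gene symbols (disjoint sets).
#' @param min_fraction Fraction of a set's markers that must be detected
#'   (default 0.5, strict inequality).
#' @return Logical vector, one flag per cell.
#' @export
flag_doublets <- function(nm, marker_table, min_fraction = 0.5) {
  if (length(marker_table) == 0) return(rep(FALSE, ncol(nm$values)))
  sym <- nm$genes$symbol
  expressed_sets <- matrix(FALSE, nrow = ncol(nm$values),
                           ncol = length(marker_table))
  for (i in seq_along(marker_table)) {
    markers <- marker_table[[i]]
    present <- markers %in% sym
    if (!all(present)) {
      warning("unknown marker gene(s) ignored: ",
              paste(markers[!present], collapse = ", "))
    }
    markers <- markers[present]
    if (!length(markers)) next
    rows <- match(markers, sym)
    frac <- Matrix::colSums(nm$values[rows, , drop = FALSE] > 0) / length(markers)
    expressed_sets[, i] <- frac > min_fraction
  }
  rowSums(expressed_sets) >= 2
}
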