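# Background-bin-corrected gene-set scoring: per cell, the mean normalized
# expression of the set minus the mean of background genes drawn from the
# same expression bins.

#' Construct a gene set
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols (duplicates removed).
#' @return A `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  stopifnot(nzchar(name), length(genes) >= 1)
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @return Named list of [gene_set()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    gene_set(f[1], f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

# Equal-count expression bins over mean expression; returns integer bin per
# gene. Ties in mean expression are broken by rank order, so bins have
# near-equal sizes even with tied means.
expression_bins <- function(gene_means, n_bins) {
  n <- length(gene_means)
  rk <- rank(gene_means, ties.method = "first")
  as.integer(ceiling(rk / n * n_bins))
}

# Draw the background genes for each foreground gene: n_background genes
# uniformly from the gene's expression bin, excluding all foreground genes,
# with replacement when the bin holds fewer candidates than n_background.
# Consumes the RNG sequentially over foreground genes in set order, so an
# independent re-implementation can reproduce the draws exactly.
sample_background <- function(gene_means, fg_idx, n_bins, n_background) {
  bins <- expression_bins(gene_means, n_bins)
  lapply(fg_idx, function(g) {
    cand <- setdiff(which(bins == bins[g]), fg_idx)
    if (!length(cand)) {
      cand <- setdiff(seq_along(gene_means), fg_idx)
    }
    if (length(cand) >= n_background) {
      cand[sample.int(length(cand), n_background)]
    } else {
      cand[sample.int(length(cand), n_background, replace = TRUE)]
    }
  })
}

#' Score a gene set with expression-matched background correction
#'
#' Per cell: the mean normalized expression over the set's genes minus the
#' mean over a pooled background. The background holds `n_background` genes
#' per foreground gene, drawn uniformly from the foreground gene's
#' expression bin (`n_bins` equal-count bins on mean expression over all
#' cells), excluding the set's own genes; bins smaller than `n_background`
#' are sampled with replacement. Set genes absent from the matrix are
#' dropped with a warning; a set with no present genes is an error.
#'
#' @param nm A [norm_matrix()].
#' @param gs A [gene_set()].
#' @param n_bins Expression bins (default 25).
#' @param n_background Background genes per foreground gene (default 100).
#' @param seed Integer seed for the background draw.
#' @return A `signature_score`: list with `name`, `scores` (per cell),
#'   `background` (list of background gene indices per foreground gene),
#'   `params`.
#' @export
score_gene_set <- function(nm, gs, n_bins = 25, n_background = 100,
                           seed = 1L) {
  sym <- nm$genes$symbol
  present <- gs$genes %in% sym
  if (!any(present)) stop("no genes of set '", gs$name, "' present in matrix")
  if (!all(present)) {
    warning("set '", gs$name, "': ", sum(!present),
            " gene(s) absent, dropped")
  }
  fg_idx <- match(gs$genes[present], sym)
  gene_means <- Matrix::rowMeans(nm$values)
  bg <- with_preserved_rng(seed,
    sample_background(gene_means, fg_idx, n_bins, n_background))
  fg_mean <- Matrix::colMeans(nm$values[fg_idx, , drop = FALSE])
  bg_idx <- unlist(bg)
  # duplicated indices replicate rows, so the pooled mean honours
  # with-replacement sampling multiplicity
  bg_mean <- Matrix::colMeans(nm$values[bg_idx, , drop = FALSE])
  scores <- as.numeric(fg_mean - bg_mean)
  names(scores) <- colnames(nm$values)
  structure(list(name = gs$name, scores = scores, foreground = fg_idx,
                 background = bg,
                 params = list(n_bins = n_bins, n_background = n_background,
                               seed = seed)),
            class = "signature_score")
}

#' Score several gene sets
#'
#' Applies [score_gene_set()] to each set with a per-set random stream
#' derived from `(seed, set name)`, so adding, removing or reordering sets
#' never perturbs the others' scores. Per-set errors are propagated as
#' warnings and the remaining sets are still scored.
#'
#' @param nm A [norm_matrix()].
#' @param sets List of [gene_set()].
#' @param n_bins,n_background See [score_gene_set()].
#' @param seed Base integer seed.
#' @return Data frame, cells x sets, of scores (0-row sets dropped).
#' @export
score_named_sets <- function(nm, sets, n_bins = 25, n_background = 100,
                             seed = 1L) {
  out <- list()
  for (gs in sets) {
    res <- tryCatch(
      score_gene_set(nm, gs, n_bins, n_background,
                     seed = derive_seed(seed, gs$name)),
      error = function(e) {
        warning("set '", gs$name, "' failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) out[[gs$name]] <- res$scores
  }
  as.data.frame(out, optional = TRUE,
                row.names = if (length(out)) names(out[[1]]) else NULL)
}
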