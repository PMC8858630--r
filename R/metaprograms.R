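# Per-sample NMF over malignant cells, robust-program filtering across
# factorization ranks, cross-sample hierarchical clustering into
# meta-programs, and core-gene extraction.

#' Prepare a sample's malignant-cell matrix for NMF
#'
#' Each gene is z-scored across the sample's cells (mean 0, sd 1),
#' zero-variance genes are dropped, and negative entries are set to zero,
#' yielding the non-negative matrix NMF expects.
#'
#' @param nm A [norm_matrix()] restricted to one sample's malignant cells.
#' @param min_cells Minimum cell count; smaller samples are rejected
#'   (default 20).
#' @return Dense non-negative gene x cell matrix.
#' @export
prepare_nmf_matrix <- function(nm, min_cells = 20) {
  n <- ncol(nm$values)
  if (n == 0) stop("no cells")
  if (n < min_cells) stop("sample below NMF cell floor (", n, " < ",
                          min_cells, ")")
  x <- as.matrix(nm$values)
  mu <- rowMeans(x)
  sd_ <- apply(x, 1L, stats::sd)
  keep <- sd_ > 0
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  z[z < 0] <- 0
  z
}

# Non-negative double SVD initialization with small-constant zero fill
# (zeros stall multiplicative updates, so they are replaced by the matrix
# mean / 100).
nndsvd_init <- function(x, k) {
  s <- svd(x, nu = k, nv = k)
  W <- matrix(0, nrow(x), k); H <- matrix(0, k, ncol(x))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
      n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        sigma <- n_up * n_vp
        if (sigma > 0) {
          W[, j] <- sqrt(s$d[j] * sigma) * up / n_up
          H[j, ] <- sqrt(s$d[j] * sigma) * vp / n_vp
        }
      } else {
        sigma <- n_un * n_vn
        W[, j] <- sqrt(s$d[j] * sigma) * un / n_un
        H[j, ] <- sqrt(s$d[j] * sigma) * vn / n_vn
      }
    }
  }
  eps <- mean(x) / 100
  W[W <= 0] <- eps; H[H <= 0] <- eps
  list(W = W, H = H)
}

#' Non-negative matrix factorization
#'
#' Frobenius-loss NMF solved by Lee-Seung multiplicative updates from a
#' non-negative double-SVD initialization (deterministic; `seed` is
#' consumed only to keep the interface uniform across stochastic stages).
#' Iterates until the relative reconstruction-error improvement falls below
#' `tol` or `max_iter` is reached; non-convergence returns the best iterate
#' with a `converged = FALSE` flag.
#'
#' @param x Non-negative matrix (genes x cells).
#' @param k Factorization rank, `1 <= k < min(dim(x))`.
#' @param seed Integer seed (interface uniformity; the solve is
#'   deterministic).
#' @param tol Relative reconstruction-error tolerance (default 1e-4).
#' @param max_iter Iteration cap (default 500).
#' @return List with `W` (genes x k), `H` (k x cells), `error` (relative
#'   Frobenius reconstruction error), `iterations`, `converged`.
#' @export
run_nmf <- function(x, k, seed = 1L, tol = 1e-4, max_iter = 500L) {
  stopifnot(k >= 1, k < min(dim(x)), all(x >= 0))
  init <- nndsvd_init(x, k)
  W <- init$W; H <- init$H
  nx <- sqrt(sum(x^2))
  err_prev <- Inf
  eps <- .Machine$double.eps
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    H <- H * (crossprod(W, x)) / (crossprod(W) %*% H + eps)
    W <- W * (x %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sqrt(sum((x - W %*% H)^2)) / nx
    if (err < 1e-10 ||
        (is.finite(err_prev) && abs(err_prev - err) <= tol * max(err, eps))) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    err_prev <- err
  }
  if (!converged) message("NMF did not converge in ", max_iter, " iterations")
  list(W = W, H = H, error = err, iterations = it, converged = converged)
}

#' Extract top-gene expression programs from NMF loadings
#'
#' One program per factor: the `top_n` genes ranked by factor loading
#' (descending), ties broken by lexicographic gene id.
#'
#' @param W Gene x factor loading matrix with gene ids as rownames.
#' @param k Factorization rank (recorded on each program).
#' @param sample_id Sample the factorization came from.
#' @param top_n Genes per program (default 50).
#' @return List of `expression_program` objects (fields: `sample_id`, `k`,
#'   `factor_index`, `genes`, `scores`).
#' @export
extract_programs <- function(W, k, sample_id, top_n = 50) {
  stopifnot(top_n <= nrow(W), !is.null(rownames(W)))
  lapply(seq_len(ncol(W)), function(j) {
    ord <- order(-W[, j], rownames(W))[seq_len(top_n)]
    structure(list(sample_id = sample_id, k = k, factor_index = j,
                   genes = rownames(W)[ord], scores = unname(W[ord, j])),
              class = "expression_program")
  })
}

#' Robust programs: stable across factorization ranks
#'
#' A program is robust when some program from the same sample at a
#' *different* rank shares at least `robust_overlap` of its `top_n` genes
#' (default 35 of 50, i.e. 70%).
#'
#' @param programs List of `expression_program` from one sample across
#'   several k values.
#' @param robust_overlap Minimum shared genes (default 35).
#' @return The robust subset, in input order.
#' @export
robust_programs <- function(programs, robust_overlap = 35) {
  ks <- vapply(programs, `[[`, 0, "k")
  keep <- vapply(seq_along(programs), function(i) {
    for (j in seq_along(programs)) {
      if (ks[j] != ks[i] &&
          length(intersect(programs[[i]]$genes, programs[[j]]$genes)) >=
            robust_overlap) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  programs[keep]
}

program_overlap_matrix <- function(programs) {
  n <- length(programs)
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ov[i, j] <- length(intersect(programs[[i]]$genes, programs[[j]]$genes))
    }
  }
  ov
}

program_id <- function(p) paste(p$sample_id, p$k, p$factor_index, sep = ".")

#' Cluster programs across samples into meta-programs
#'
#' Pairwise distance between programs is `top_n` minus the number of shared
#' top genes; average-linkage hierarchical clustering is cut at `cut_height`
#' (default `top_n - robust_overlap` = 15, keeping the meta-program
#' criterion commensurate with the robustness criterion). Clusters whose
#' members span at least 2 samples become meta-programs; core genes are
#' attached via [core_genes()].
#'
#' @param programs List of (robust) `expression_program` across samples.
#' @param top_n Program length (default 50).
#' @param cut_height Dendrogram cut height (default 15).
#' @param core_frac Core-gene membership fraction (default 0.25).
#' @return List with `metaprograms` (list of `meta_program`: `members`,
#'   `member_ids`, `core_genes`, `label`) and `tree` (the `hclust`, NULL
#'   when fewer than 2 programs).
#' @export
cluster_programs <- function(programs, top_n = 50, cut_height = top_n - 35,
                             core_frac = 0.25) {
  if (length(programs) < 2) {
    return(list(metaprograms = list(), tree = NULL))
  }
  ids <- vapply(programs, program_id, "")
  ov <- program_overlap_matrix(programs)
  d <- top_n - ov
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  mps <- list()
  for (g in sort(unique(cl))) {
    members <- programs[cl == g]
    n_samples <- length(unique(vapply(members, `[[`, "", "sample_id")))
    if (n_samples < 2) next
    mp <- structure(list(members = members,
                         member_ids = ids[cl == g],
                         core_genes = character(), label = NA_character_),
                    class = "meta_program")
    mp$core_genes <- core_genes(mp, core_frac)
    mps[[length(mps) + 1L]] <- mp
  }
  list(metaprograms = mps, tree = tree)
}

#' Core genes of a meta-program
#'
#' A gene is core when it appears in at least `ceiling(core_frac * m)` of
#' the `m` member programs and those appearances span at least 2 samples.
#'
#' @param mp A `meta_program`.
#' @param core_frac Membership fraction (default 0.25).
#' @return Character vector of core gene ids (sorted).
#' @export
core_genes <- function(mp, core_frac = 0.25) {
  members <- mp$members
  m <- length(members)
  stopifnot(m >= 2)
  gene_tab <- table(unlist(lapply(members, `[[`, "genes")))
  need <- ceiling(core_frac * m)
  cand <- names(gene_tab)[gene_tab >= need]
  sample_of <- vapply(members, `[[`, "", "sample_id")
  keep <- vapply(cand, function(g) {
    hits <- vapply(members, function(p) g %in% p$genes, logical(1))
    length(unique(sample_of[hits])) >= 2
  }, logical(1))
  sort(cand[keep])
}

#' Discover meta-programs across a cohort's malignant cells
#'
#' The full per-sample procedure: for each sample with enough malignant
#' cells, restrict to the chosen genes, prepare the non-negative matrix,
#' factorize at every rank in `k_range`, take the top-`top_n` programs per
#' factor, keep the rank-robust ones, then cluster the robust programs of
#' the GG and solid pools separately into meta-programs (pools are matched
#' by core-gene overlap only for reporting).
#'
#' @param nm A multi-sample [norm_matrix()] of malignant cells.
#' @param genes_use Optional gene ids to restrict to (e.g. variable genes).
#' @param k_range Integer ranks (default 6:9).
#' @param top_n,robust_overlap,core_frac,min_cells See the stage functions.
#' @param seed Integer seed.
#' @return List with per-pool results (`GG`, `solid`: `programs`, `robust`,
#'   `metaprograms`, `tree`) and `pool_matching` (core-gene overlap between
#'   pools' meta-programs).
#' @export
discover_metaprograms <- function(nm, genes_use = NULL, k_range = 6:9,
                                  top_n = 50, robust_overlap = 35,
                                  core_frac = 0.25, min_cells = 20,
                                  seed = 1L) {
  if (!is.null(genes_use)) {
    nm <- norm_matrix(nm$values[nm$genes$gene_id %in% genes_use, , drop = FALSE],
                      nm$genes[nm$genes$gene_id %in% genes_use, , drop = FALSE],
                      nm$cells, nm$scale_factor)
  }
  pools <- list()
  for (grp in intersect(c("GG", "solid"), unique(nm$cells$group))) {
    progs <- list(); robust <- list()
    for (sid in unique(nm$cells$sample_id[nm$cells$group == grp])) {
      sub <- subset_cells(nm, nm$cells$sample_id == sid)
      x <- tryCatch(prepare_nmf_matrix(sub, min_cells = min_cells),
                    error = function(e) {
                      message("skipping sample ", sid, ": ",
                              conditionMessage(e))
                      NULL
                    })
      if (is.null(x) || nrow(x) < top_n) next
      sample_programs <- list()
      for (k in k_range) {
        if (k >= min(dim(x))) next
        fit <- run_nmf(x, k, seed = derive_seed(seed, paste0(sid, ".k", k)))
        sample_programs <- c(sample_programs,
                             extract_programs(fit$W, k, sid, top_n = top_n))
      }
      progs <- c(progs, sample_programs)
      robust <- c(robust, robust_programs(sample_programs, robust_overlap))
    }
    cl <- cluster_programs(robust, top_n = top_n,
                           cut_height = top_n - robust_overlap,
                           core_frac = core_frac)
    pools[[grp]] <- list(programs = progs, robust = robust,
                         metaprograms = cl$metaprograms, tree = cl$tree)
  }
  matching <- NULL
  if (all(c("GG", "solid") %in% names(pools))) {
    a <- pools$GG$metaprograms; b <- pools$solid$metaprograms
    if (length(a) && length(b)) {
      matching <- expand.grid(GG = seq_along(a), solid = seq_along(b))
      matching$core_overlap <- mapply(function(i, j) {
        length(intersect(a[[i]]$core_genes, b[[j]]$core_genes))
      }, matching$GG, matching$solid)
    }
  }
  c(pools, list(pool_matching = matching))
}

#' Write a program dendrogram as Newick text
#'
#' @param tree An `hclust` from [cluster_programs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_program_tree <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
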