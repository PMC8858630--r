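# Simplified ligand-receptor communication scoring between labeled cell
# groups with a one-sided permutation test. The score is a declared
# geometric-mean / Hill formulation: it keeps the two properties the
# downstream figures rely on (probability 0 when either side is silent,
# monotone saturation), without the external package's full mass-action
# model.

#' Ligand-receptor pair
#'
#' @param ligand Character vector of ligand subunit gene symbols.
#' @param receptor Character vector of receptor subunit gene symbols
#'   (multi-subunit receptors allowed).
#' @param pathway Optional pathway name.
#' @return An `lr_pair`.
#' @export
lr_pair <- function(ligand, receptor, pathway = NA_character_) {
  stopifnot(length(ligand) >= 1, length(receptor) >= 1)
  structure(list(ligand = as.character(ligand),
                 receptor = as.character(receptor), pathway = pathway),
            class = "lr_pair")
}

#' Read a ligand-receptor pair table
#'
#' TSV with header `pathway`, `ligand`, `receptor`; subunits joined by ";".
#'
#' @param path TSV file.
#' @return List of [lr_pair()].
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    lr_pair(strsplit(df$ligand[i], ";", fixed = TRUE)[[1]],
            strsplit(df$receptor[i], ";", fixed = TRUE)[[1]],
            df$pathway[i])
  })
}

# Per-cell geometric mean over a gene set's normalized values; cells where
# any subunit is 0 get 0 (multi-subunit complexes need every subunit).
subunit_geomean <- function(nm, genes) {
  rows <- match(genes, nm$genes$symbol)
  if (anyNA(rows)) return(NULL)
  vals <- as.matrix(nm$values[rows, , drop = FALSE])
  exp(colMeans(log(vals))) # log(0) -> -Inf -> geomean 0
}

#' Communication probability for one pair and one direction
#'
#' `L` is the mean over sender cells of the per-cell geometric mean of the
#' ligand subunits' normalized expression; `R` likewise for the receiver
#' and receptor. The probability is the Hill form `L*R / (Kh + L*R)`, which
#' is 0 exactly when either side's mean expression is 0 and saturates to 1.
#' Pairs with genes absent from the matrix score 0 with a "gene-missing"
#' flag.
#'
#' @param nm A [norm_matrix()].
#' @param labels Per-cell group labels.
#' @param pair An [lr_pair()].
#' @param sender,receiver Group labels (non-empty groups).
#' @param hill_constant Hill constant `Kh` (default 0.5).
#' @return Numeric probability in `[0, 1]`; attribute `flag` is
#'   "gene-missing" when pair genes are absent.
#' @export
communication_probability <- function(nm, labels, pair, sender, receiver,
                                      hill_constant = 0.5) {
  stopifnot(length(labels) == ncol(nm$values))
  s_idx <- which(labels == sender); r_idx <- which(labels == receiver)
  stopifnot(length(s_idx) >= 1, length(r_idx) >= 1)
  lig <- subunit_geomean(nm, pair$ligand)
  rec <- subunit_geomean(nm, pair$receptor)
  if (is.null(lig) || is.null(rec)) {
    out <- 0
    attr(out, "flag") <- "gene-missing"
    return(out)
  }
  L <- mean(lig[s_idx]); R <- mean(rec[r_idx])
  L * R / (hill_constant + L * R)
}

#' Permutation test for ligand-receptor communication
#'
#' For every (pair, sender, receiver) combination the observed probability
#' is compared against `n_perm` global shuffles of the cell group labels;
#' all combinations share one permutation stream per seed. The one-sided
#' p-value is `(1 + #{permuted >= observed}) / (1 + n_perm)`; an observed
#' probability of 0 gets p = 1 by convention with a flag. Groups with fewer
#' than `min_group_cells` cells are skipped.
#'
#' @param nm A [norm_matrix()].
#' @param labels Per-cell group labels.
#' @param pairs List of [lr_pair()].
#' @param sender_receiver Optional 2-column data frame of (sender,
#'   receiver) label combinations; default: all ordered pairs of observed
#'   labels.
#' @param n_perm Number of permutations (default 999).
#' @param hill_constant Hill constant (default 0.5).
#' @param min_group_cells Minimum cells per group (default 10).
#' @param seed Integer seed.
#' @return Data frame: `pathway`, `ligand`, `receptor`, `sender`,
#'   `receiver`, `probability`, `p`, `p_adj` (BH within each
#'   sender-receiver family), `flag`.
#' @export
lr_permutation_test <- function(nm, labels, pairs, sender_receiver = NULL,
                                n_perm = 999, hill_constant = 0.5,
                                min_group_cells = 10, seed = 1L) {
  stopifnot(n_perm >= 1)
  labels <- as.character(labels)
  counts <- table(labels)
  groups <- names(counts)[counts >= min_group_cells]
  if (is.null(sender_receiver)) {
    sender_receiver <- expand.grid(sender = groups, receiver = groups,
                                   stringsAsFactors = FALSE)
  } else {
    ok <- sender_receiver$sender %in% groups &
      sender_receiver$receiver %in% groups
    sender_receiver <- sender_receiver[ok, , drop = FALSE]
  }
  # per-cell subunit geometric means, computed once
  ligs <- lapply(pairs, function(p) subunit_geomean(nm, p$ligand))
  recs <- lapply(pairs, function(p) subunit_geomean(nm, p$receptor))
  prob_of <- function(lab) {
    idx <- split(seq_along(lab), lab)
    out <- matrix(0, length(pairs), nrow(sender_receiver))
    for (i in seq_along(pairs)) {
      if (is.null(ligs[[i]]) || is.null(recs[[i]])) next
      Lg <- vapply(idx, function(ii) mean(ligs[[i]][ii]), numeric(1))
      Rg <- vapply(idx, function(ii) mean(recs[[i]][ii]), numeric(1))
      L <- Lg[sender_receiver$sender]; R <- Rg[sender_receiver$receiver]
      out[i, ] <- L * R / (hill_constant + L * R)
    }
    out
  }
  obs <- prob_of(labels)
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  with_preserved_rng(seed, {
    for (b in seq_len(n_perm)) {
      perm <- prob_of(sample(labels))
      exceed <- exceed + (perm >= obs)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  rows <- list()
  for (j in seq_len(nrow(sender_receiver))) {
    fam_p <- p[, j]
    fam_p[obs[, j] == 0] <- 1
    rows[[j]] <- data.frame(
      pathway = vapply(pairs, function(x) x$pathway %||% NA_character_, ""),
      ligand = vapply(pairs, function(x) paste(x$ligand, collapse = ";"), ""),
      receptor = vapply(pairs, function(x) paste(x$receptor, collapse = ";"), ""),
      sender = sender_receiver$sender[j],
      receiver = sender_receiver$receiver[j],
      probability = obs[, j], p = fam_p, p_adj = bh_adjust(fam_p),
      flag = ifelse(vapply(seq_along(pairs),
                           function(i) is.null(ligs[[i]]) || is.null(recs[[i]]),
                           logical(1)), "gene-missing",
                    ifelse(obs[, j] == 0, "zero-probability", "")),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
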