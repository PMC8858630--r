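# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a base seed and a label
#'
#' All stochastic stages take an integer seed; stages that need independent
#' random streams (one per gene set, one per sample, ...) derive a child seed
#' from the base seed plus a string label, so adding or reordering streams
#' never perturbs the others. The result always fits in a 32-bit integer.
#'
#' @param seed Integer base seed.
#' @param label Character scalar naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer((abs(seed) %% m * 7919 + h) %% m)
}

# Natural chromosome order: 1..22, X, Y, MT, then anything else alphabetically.
# Accepts names with or without a "chr" prefix.
chromosome_rank <- function(chrom) {
  stripped <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(stripped))
  rank <- ifelse(!is.na(num), num,
                 ifelse(toupper(stripped) == "X", 100,
                        ifelse(toupper(stripped) == "Y", 101,
                               ifelse(toupper(stripped) %in% c("M", "MT"), 102, NA))))
  other <- is.na(rank)
  if (any(other)) {
    rank[other] <- 200 + match(stripped[other], sort(unique(stripped[other])))
  }
  rank
}

#' Genome ordering of genes
#'
#' Returns the permutation putting genes in (chromosome, start, gene id)
#' order, with chromosomes in natural order 1..22, X, Y.
#'
#' @param genes Data frame with columns `chromosome`, `start`, `gene_id`.
#' @return Integer permutation of `seq_len(nrow(genes))`.
#' @export
genome_order <- function(genes) {
  order(chromosome_rank(genes$chromosome), genes$start, genes$gene_id)
}

# Centered moving average along a vector with window shrinking at the edges
# (and to the vector length when the vector is shorter than the window).
# Operates column-wise on a matrix: each column smoothed independently along
# rows. Implemented with cumulative sums so cost is linear.
running_mean <- function(x, window) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  h <- (window - 1L) %/% 2L
  cs <- apply(x, 2L, cumsum)
  cs <- rbind(0, matrix(cs, nrow = n))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  out
}

# Stage log line used by the pipeline: name, counts, elapsed seconds.
stage_log <- function(stage, ..., t0 = NULL) {
  info <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(info), unlist(info), sep = "=", collapse = " "))
  if (!is.null(t0)) {
    msg <- paste0(msg, sprintf(" wall=%.2fs", as.numeric(Sys.time()) - t0))
  }
  message(msg)
  invisible(msg)
}
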