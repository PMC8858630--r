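# Independent loop-based implementation of the score definition; it reuses
# only the seeded background draw (part of the definition) and computes
# every mean with explicit loops.
loop_score <- function(nm, gs, n_bins, n_background, seed) {
  v <- as.matrix(nm$values)
  sym <- nm$genes$symbol
  fg <- match(gs$genes[gs$genes %in% sym], sym)
  means <- numeric(nrow(v))
  for (g in seq_len(nrow(v))) means[g] <- mean(v[g, ])
  bins <- as.integer(ceiling(rank(means, ties.method = "first") /
                               length(means) * n_bins))
  set.seed(seed)
  bgl <- list()
  for (i in seq_along(fg)) {
    cand <- setdiff(which(bins == bins[fg[i]]), fg)
    bgl[[i]] <- if (length(cand) >= n_background) {
      cand[sample.int(length(cand), n_background)]
    } else {
      cand[sample.int(length(cand), n_background, replace = TRUE)]
    }
  }
  out <- numeric(ncol(v))
  for (cell in seq_len(ncol(v))) {
    fsum <- 0
    for (g in fg) fsum <- fsum + v[g, cell]
    bsum <- 0; nb <- 0L
    for (i in seq_along(fg)) {
      for (b in bgl[[i]]) { bsum <- bsum + v[b, cell]; nb <- nb + 1L }
    }
    out[cell] <- fsum / length(fg) - bsum / nb
  }
  out
}
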