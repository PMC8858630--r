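# Composition tables and the statistical comparisons used throughout:
# two-sided unpaired/paired Wilcoxon with Benjamini-Hochberg adjustment,
# and the random-intercept linear mixed model
# score ~ group + (1 | patient), REML, with Satterthwaite degrees of
# freedom for the fixed-effect tests.

#' Per-sample cell-type composition
#'
#' Fractions of each cell type per sample, over a stated denominator (e.g.
#' immune cell types only, or all types). Types outside the denominator are
#' excluded from both numerator and denominator; samples with zero
#' denominator cells are dropped with a message.
#'
#' @param cells Data frame with `sample_id` and `label` per cell.
#' @param sample_meta Data frame with `sample_id`, `patient_id`, `group`.
#' @param denominator_types Character vector of types forming the
#'   denominator (default: all observed labels).
#' @return Data frame: one row per sample with `sample_id`, `patient_id`,
#'   `group`, then one fraction column per denominator type; fraction rows
#'   sum to 1.
#' @export
composition_table <- function(cells, sample_meta,
                              denominator_types = NULL) {
  denominator_types <- denominator_types %||% sort(unique(cells$label))
  sub <- cells[cells$label %in% denominator_types, , drop = FALSE]
  tab <- table(factor(sub$sample_id, levels = sample_meta$sample_id),
               factor(sub$label, levels = denominator_types))
  totals <- rowSums(tab)
  drop <- totals == 0
  if (any(drop)) {
    message(sum(drop), " sample(s) with zero denominator cells dropped: ",
            paste(rownames(tab)[drop], collapse = ", "))
  }
  frac <- sweep(tab[!drop, , drop = FALSE], 1, totals[!drop], "/")
  meta <- sample_meta[match(rownames(frac), sample_meta$sample_id), ,
                      drop = FALSE]
  out <- cbind(meta[, c("sample_id", "patient_id", "group")],
               as.data.frame.matrix(frac))
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum / signed-rank test
#'
#' Unpaired: Mann-Whitney rank-sum with midranks for ties; exact
#' enumeration when the combined sample size is at most 12 and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction. Paired: signed-rank on the differences with zeros dropped;
#' exact when at most 15 nonzero differences with no ties in their absolute
#' values, otherwise the corrected normal approximation. All differences
#' zero yields p = 1 with a flag.
#'
#' @param x,y Numeric samples (equal length when `paired`).
#' @param paired Logical.
#' @return List: `statistic`, `p.value`, `exact`, `method`,
#'   `all_zero` (paired degenerate flag).
#' @export
wilcoxon_test <- function(x, y, paired = FALSE) {
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    nz <- d[d != 0]
    if (!length(nz)) {
      return(list(statistic = NA_real_, p.value = 1, exact = TRUE,
                  method = "wilcoxon_signed_rank", all_zero = TRUE))
    }
    exact <- length(nz) <= 15 && !anyDuplicated(abs(nz)) &&
      length(nz) == length(d)
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         exact = exact, method = "wilcoxon_signed_rank", all_zero = FALSE)
  } else {
    stopifnot(length(x) >= 1, length(y) >= 1)
    exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         exact = exact, method = "wilcoxon_rank_sum", all_zero = FALSE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, capped at 1.
#'
#' @param pvals Numeric vector in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

# Sufficient statistics of the random-intercept model for one variance
# ratio lambda = var_patient / var_residual: per-patient blocks give
# V_i^{-1} = I - lambda/(1 + lambda n_i) J_i in O(N).
lmm_suffstats <- function(y, X, patient, lambda) {
  pats <- split(seq_along(y), patient)
  p <- ncol(X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); yty <- 0; logdetV <- 0
  for (idx in pats) {
    ni <- length(idx)
    Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
    a <- lambda / (1 + lambda * ni)
    sx <- colSums(Xi); sy <- sum(yi)
    XtVX <- XtVX + crossprod(Xi) - a * tcrossprod(sx)
    XtVy <- XtVy + crossprod(Xi, yi) - a * sx * sy
    yty <- yty + sum(yi^2) - a * sy^2
    logdetV <- logdetV + log1p(lambda * ni)
  }
  list(XtVX = XtVX, XtVy = as.numeric(XtVy), yty = yty, logdetV = logdetV)
}

# Profiled REML criterion in lambda (negated for minimization).
lmm_profile_negreml <- function(lambda, y, X, patient) {
  n <- length(y); p <- ncol(X)
  s <- lmm_suffstats(y, X, patient, lambda)
  beta <- solve(s$XtVX, s$XtVy)
  rss <- s$yty - sum(beta * s$XtVy)
  0.5 * ((n - p) * log(max(rss, 1e-300)) + s$logdetV +
           determinant(s$XtVX, logarithm = TRUE)$modulus[1])
}

# Full REML log-likelihood in theta = (var_patient, var_residual), up to an
# additive constant; used for the observed-information Hessian.
lmm_reml_loglik <- function(theta, y, X, patient) {
  vp <- theta[1]; ve <- theta[2]
  if (ve <= 0 || vp < -ve / max(table(patient))) return(-Inf)
  lambda <- vp / ve
  n <- length(y); p <- ncol(X)
  s <- lmm_suffstats(y, X, patient, lambda)
  beta <- solve(s$XtVX, s$XtVy)
  rss <- s$yty - sum(beta * s$XtVy)   # y' (I + lambda ZZ')^-1 y residual form
  -0.5 * (n * log(ve) + s$logdetV + rss / ve +
            determinant(s$XtVX / ve, logarithm = TRUE)$modulus[1])
}

# Variance of the contrast c'beta as a function of theta.
lmm_contrast_var <- function(theta, y, X, patient, contrast) {
  lambda <- theta[1] / theta[2]
  s <- lmm_suffstats(y, X, patient, lambda)
  theta[2] * as.numeric(crossprod(contrast, solve(s$XtVX, contrast)))
}

#' Random-intercept linear mixed model with Satterthwaite tests
#'
#' Fits `score ~ group + (1 | patient)` by REML: the variance ratio
#' `var_patient / var_residual` is profiled out and optimized in one
#' dimension (bounded at the zero boundary, tolerance 1e-8), giving exact
#' GLS fixed effects at the optimum. For each non-reference group level,
#' the t statistic uses Satterthwaite degrees of freedom
#' `2 f^2 / (g' A g)`, where `f` is the contrast variance, `g` its
#' gradient in the variance components (central finite differences), and
#' `A` the inverse observed REML information (numeric Hessian).
#' Treatment coding with `"nLung"` as reference when present, else
#' `"GG"`, else the first level.
#'
#' @param score Per-cell numeric response.
#' @param group Per-cell group factor (at least 2 levels).
#' @param patient Per-cell patient factor (at least 2 patients).
#' @param reference Optional reference level override.
#' @return Data frame of class `lmm_result`, one row per contrast:
#'   `contrast`, `estimate`, `se`, `df`, `t`, `p`, plus attributes
#'   `var_patient`, `var_residual`, `boundary` (TRUE when the patient
#'   variance is estimated at 0).
#' @export
fit_lmm <- function(score, group, patient, reference = NULL) {
  group <- factor(group); patient <- factor(patient)
  stopifnot(length(score) == length(group), length(score) == length(patient),
            nlevels(group) >= 2, nlevels(patient) >= 2)
  ref <- reference %||%
    (if ("nLung" %in% levels(group)) "nLung"
     else if ("GG" %in% levels(group)) "GG" else levels(group)[1])
  group <- stats::relevel(group, ref = ref)
  X <- stats::model.matrix(~ group)
  y <- as.numeric(score)
  n <- length(y); p <- ncol(X)
  obj <- function(l) lmm_profile_negreml(l, y, X, patient)
  opt <- stats::optimize(obj, interval = c(0, 1e5), tol = 1e-8)
  lambda <- if (obj(0) <= opt$objective) 0 else opt$minimum
  s <- lmm_suffstats(y, X, patient, lambda)
  beta <- solve(s$XtVX, s$XtVy)
  rss <- s$yty - sum(beta * s$XtVy)
  ve <- rss / (n - p)
  vp <- lambda * ve
  theta <- c(vp, ve)
  # observed information by central finite differences on the REML surface
  h <- pmax(abs(theta) * 1e-4, 1e-7)
  ll <- function(th) lmm_reml_loglik(th, y, X, patient)
  H <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- (ll(theta + ei + ej) - ll(theta + ei - ej) -
                    ll(theta - ei + ej) + ll(theta - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  A <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 2, 2))
  rows <- list()
  for (j in 2:p) {
    cvec <- numeric(p); cvec[j] <- 1
    f <- lmm_contrast_var(theta, y, X, patient, cvec)
    g <- vapply(1:2, function(i) {
      ei <- c(0, 0); ei[i] <- h[i]
      (lmm_contrast_var(theta + ei, y, X, patient, cvec) -
         lmm_contrast_var(theta - ei, y, X, patient, cvec)) / (2 * h[i])
    }, numeric(1))
    denom <- as.numeric(crossprod(g, A %*% g))
    df <- if (is.finite(denom) && denom > 0) 2 * f^2 / denom else n - p
    est <- beta[j]; se <- sqrt(f)
    tstat <- est / se
    rows[[j - 1]] <- data.frame(
      contrast = paste0(colnames(X)[j], "_vs_", ref),
      estimate = est, se = se, df = df, t = tstat,
      p = 2 * stats::pt(-abs(tstat), df), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "var_patient") <- vp
  attr(out, "var_residual") <- ve
  attr(out, "boundary") <- lambda == 0
  class(out) <- c("lmm_result", class(out))
  out
}
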