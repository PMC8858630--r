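test_that("composition fractions follow the stated arithmetic", {
  cells <- data.frame(sample_id = rep("S1", 4), label = c("T", "T", "T", "B"))
  meta <- data.frame(sample_id = "S1", patient_id = "P1", group = "GG")
  tab <- composition_table(cells, meta, c("T", "B"))
  expect_equal(tab$T, 0.75)
  expect_equal(tab$B, 0.25)
})

test_that("composition rows sum to one and empty samples are dropped", {
  cells <- data.frame(sample_id = c(rep("S1", 6), rep("S2", 3)),
                      label = c("T", "T", "B", "NK", "NK", "NK",
                                "Epi", "Epi", "Epi"))
  meta <- data.frame(sample_id = c("S1", "S2"), patient_id = c("P1", "P2"),
                     group = c("GG", "solid"))
  tab <- composition_table(cells, meta)
  frac <- tab[, setdiff(names(tab), c("sample_id", "patient_id", "group"))]
  expect_equal(unname(rowSums(frac)), rep(1, nrow(tab)))
  # immune-only denominator: S2 has no immune cells and is dropped
  expect_message(tab2 <- composition_table(cells, meta, c("T", "B", "NK")),
                 "dropped")
  expect_equal(tab2$sample_id, "S1")
})

test_that("planted abundance shifts order the group means as configured", {
  fx <- metaprogram_fixture()
  truth <- fx$cohort$truth
  meta <- unique(truth[, c("sample_id", "patient_id", "group")])
  tab <- composition_table(
    data.frame(sample_id = truth$sample_id, label = truth$cell_type), meta)
  mal_by_group <- tapply(tab$Malignant, tab$group, mean)
  expect_true(mal_by_group[["solid"]] > mal_by_group[["GG"]])
  t_by_group <- tapply(tab$T, tab$group, mean)
  expect_true(t_by_group[["GG"]] > t_by_group[["solid"]])
})

test_that("Wilcoxon exact paths reproduce enumerable p-values", {
  w <- wilcoxon_test(c(1, 2), c(3, 4))
  expect_true(w$exact)
  expect_equal(w$p.value, 1 / 3)    # 2 of 6 rank arrangements as extreme
  # paired, n = 5 distinct positive differences: p = 2 / 2^5
  w2 <- wilcoxon_test(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5), paired = TRUE)
  expect_true(w2$exact)
  expect_equal(w2$p.value, 0.0625)
  # all differences zero: degenerate, p = 1
  w3 <- wilcoxon_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(w3$p.value, 1)
  expect_true(w3$all_zero)
})

test_that("exact and approximate Wilcoxon agree within the sanity band at n = 12", {
  set.seed(12)
  for (i in 1:20) {
    x <- sample(100, 6)
    y <- sample(100, 6) + 0.5     # guaranteed distinct from x and within y
    pe <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    pa <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE)$p.value)
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("BH adjustment matches the step-up formula and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("the mixed model matches lmerTest on a general two-group fit", {
  set.seed(42)
  np <- 6; q <- 30
  patient <- rep(sprintf("P%d", 1:np), each = q)
  group <- rep(rep(c("GG", "solid"), length.out = np), each = q)
  y <- (group == "solid") + rep(rnorm(np, 0, 0.5), each = q) + rnorm(np * q)
  fit <- fit_lmm(y, group, patient)
  lf <- lmerTest::lmer(y ~ g + (1 | p),
                       data = data.frame(y = y, g = group, p = patient),
                       REML = TRUE)
  co <- coef(summary(lf))["gsolid", ]
  expect_equal(fit$estimate, unname(co["Estimate"]), tolerance = 1e-6)
  expect_equal(fit$se, unname(co["Std. Error"]), tolerance = 1e-6)
  expect_equal(fit$df, unname(co["df"]), tolerance = 1e-3)
  expect_equal(fit$p, unname(co["Pr(>|t|)"]), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(attr(fit, "var_patient"), vc$vcov[1], tolerance = 1e-6)
  expect_equal(attr(fit, "var_residual"), vc$vcov[2], tolerance = 1e-6)
})

test_that("with zero patient variance the fit collapses to the pooled t-test", {
  set.seed(1)
  r <- as.numeric(scale(rnorm(10)))
  y <- rep(r, 8) + rep(c(0, 1), each = 40)
  group <- rep(c("GG", "solid"), each = 40)
  patient <- rep(sprintf("P%d", 1:8), each = 10)
  fit <- fit_lmm(y, group, patient)
  expect_true(attr(fit, "boundary"))
  tt <- stats::t.test(y ~ group, var.equal = TRUE)
  expect_equal(fit$estimate, unname(tt$estimate[2] - tt$estimate[1]),
               tolerance = 1e-9)
  expect_equal(fit$se, unname(abs(diff(tt$estimate)) / abs(tt$statistic)),
               tolerance = 1e-9)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-9)
  expect_lt(abs(fit$df - (length(y) - 2)), 0.5)
})

test_that("the REML objective at the optimum dominates the OLS point", {
  set.seed(10)
  patient <- rep(sprintf("P%d", 1:5), each = 12)
  group <- rep(c("GG", "solid", "GG", "solid", "GG"), each = 12)
  y <- rep(rnorm(5, 0, 1), each = 12) + rnorm(60)
  fit <- fit_lmm(y, group, patient)
  X <- stats::model.matrix(~ factor(group))
  ols_ve <- sum(stats::lm.fit(X, y)$residuals^2) / (60 - 2)
  ll_opt <- psnpipe:::lmm_reml_loglik(
    c(attr(fit, "var_patient"), attr(fit, "var_residual")), y, X,
    factor(patient))
  ll_ols <- psnpipe:::lmm_reml_loglik(c(0, ols_ve), y, X, factor(patient))
  expect_gte(ll_opt, ll_ols - 1e-8)
})

test_that("three-level fits report one contrast per non-reference group", {
  set.seed(11)
  patient <- rep(sprintf("P%d", 1:6), each = 10)
  group <- rep(c("nLung", "GG", "solid"), each = 20)
  y <- rnorm(60) + (group == "solid") * 0.5
  fit <- fit_lmm(y, group, patient)
  expect_equal(nrow(fit), 2)
  expect_true(all(grepl("vs_nLung", fit$contrast)))
  expect_error(fit_lmm(y, rep("GG", 60), patient))
})
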