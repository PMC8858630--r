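test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_patients = 1, nlung_patients = 0,
                       n_cells_per_sample = 60, n_genes = 600, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_true(isTRUE(all.equal(a$samples[[1]], b$samples[[1]])))
  expect_identical(a$truth, b$truth)
})

test_that("planted QC violation classes appear in the stated numbers and trip their rule", {
  ch <- qc_fixture()
  truth <- ch$truth
  # 0.05/0.03/0.05/0.02 of 500 cells per sample
  per_sample <- table(truth$sample_id, truth$qc_class)
  for (s in rownames(per_sample)) {
    expect_equal(unname(per_sample[s, "low_genes"]), 25)
    expect_equal(unname(per_sample[s, "high_genes"]), 15)
    expect_equal(unname(per_sample[s, "high_mito"]), 25)
    expect_equal(unname(per_sample[s, "high_umi"]), 10)
  }
  for (m in ch$samples) {
    qc <- cell_qc_metrics(m)
    cls <- truth$qc_class[truth$sample_id == m$sample_id]
    expect_true(all(qc$n_genes[cls == "low_genes"] < 200))
    expect_true(all(qc$n_genes[cls == "high_genes"] > 6000))
    expect_true(all(qc$mito_frac[cls == "high_mito"] > 0.15))
    expect_true(all(qc$n_umis[cls == "high_umi"] > 60000))
  }
})

test_that("a planted fold-2 chr1 segment shifts malignant counts by roughly that fold", {
  cfg <- cohort_config(n_patients = 1, nlung_patients = 0,
                       n_cells_per_sample = 600, n_genes = 2000,
                       cnv_spec = list(list(chromosome = "1", fold = 2,
                                            carrier = "Malignant")),
                       program_spec = list(), signature_shift_spec = list(),
                       qc_contaminant_fractions = c(low_genes = 0),
                       seed = 21)
  ch <- simulate_cohort(cfg)
  seg <- ch$gene_truth$gene_id[!is.na(ch$gene_truth$cnv_segment)]
  counts <- do.call(cbind, lapply(ch$samples, function(m) m$counts))
  truth <- ch$truth
  mal <- truth$malignant
  seg_rows <- match(seg, ch$samples[[1]]$genes$gene_id)
  ratio <- mean(Matrix::rowMeans(counts[seg_rows, mal, drop = FALSE])) /
    mean(Matrix::rowMeans(counts[seg_rows, !mal & truth$cell_type ==
                                   "Epithelial", drop = FALSE]))
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("carrier cells have higher expected expression on amplified segments (generator means)", {
  cfg <- cohort_config(n_patients = 1, n_cells_per_sample = 10, seed = 3)
  panel <- cfg$gene_panel
  seg_idx <- which(panel$chromosome == "1")
  p_mal <- psnpipe:::cell_probability(cfg, "Malignant", TRUE,
                                      rep(0, 3), "GG", 0.05)
  p_epi <- psnpipe:::cell_probability(cfg, "Epithelial", FALSE,
                                      rep(0, 3), "GG", 0.05)
  expect_true(all(p_mal[seg_idx] > p_epi[seg_idx]))
  # deletion segment: carrier strictly lower
  del_idx <- which(panel$chromosome == "5")
  expect_true(all(p_mal[del_idx] < p_epi[del_idx]))
})

test_that("default cohort counts are non-negative integers and sparse", {
  cfg <- cohort_config(n_patients = 1, nlung_patients = 1,
                       n_cells_per_sample = 150, seed = 12)
  ch <- simulate_cohort(cfg)
  for (m in ch$samples) {
    x <- m$counts
    expect_true(all(x@x >= 0))
    expect_true(all(x@x == round(x@x)))
    expect_gt(1 - length(x@x) / prod(dim(x)), 0.5)
  }
})

test_that("program gene lists referencing unknown genes are rejected", {
  expect_error(
    cohort_config(program_spec = list(list(name = "bad",
                                           genes = paste0("NOPE", 1:50),
                                           on_prob = 0.3, amplitude = 2))),
    "unknown genes")
})

test_that("fixtures round-trip losslessly and regenerate identically", {
  cfg <- cohort_config(n_patients = 1, nlung_patients = 0,
                       n_cells_per_sample = 40, n_genes = 400,
                       program_spec = list(), signature_shift_spec = list(),
                       seed = 77)
  ch <- simulate_cohort(cfg)
  d1 <- withr::local_tempdir()
  write_fixture(ch, d1)
  rt <- read_fixture(d1)
  for (s in names(ch$samples)) {
    expect_true(isTRUE(all.equal(ch$samples[[s]], rt$samples[[s]])))
  }
  # regenerating from the recorded config + seed gives identical files
  d2 <- withr::local_tempdir()
  write_fixture(simulate_cohort(cfg), d2)
  f1 <- file.path(d1, ch$samples[[1]]$sample_id, "matrix.mtx")
  f2 <- file.path(d2, ch$samples[[1]]$sample_id, "matrix.mtx")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an empty sample writes a valid, readable triplet", {
  m <- toy_count_matrix(matrix(0, 3, 0))
  d <- withr::local_tempdir()
  write_mtx_triplet(m, d)
  rt <- read_mtx_triplet(d)
  expect_equal(dim(rt$counts), c(3L, 0L))
})

test_that("planted group-abundance differences give the composition test high power", {
  # the generator draws each cell's type from the group's abundance
  # weights before any counts are generated, so simulating that label
  # layer directly is exactly the generator's composition model
  cfg <- cohort_config(n_patients = 2, n_cells_per_sample = 10, seed = 1)
  w <- cfg$cell_type_spec$weights
  set.seed(42)
  hits <- replicate(200, {
    comp <- do.call(rbind, lapply(1:12, function(p) {
      vapply(c("GG", "solid"), function(g) {
        mean(sample(names(w[[g]]), 200, replace = TRUE,
                    prob = w[[g]]) == "T")
      }, numeric(1))
    }))
    wilcoxon_test(comp[, "GG"], comp[, "solid"])$p.value < 0.05
  })
  expect_gt(mean(hits), 0.8)
})
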