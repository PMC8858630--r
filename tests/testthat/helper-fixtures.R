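# Shared fixtures, memoized so expensive cohorts are simulated once per run.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# dense-random normalized matrix (not cohort-structured) for unit tests
rand_norm_matrix <- function(ng, nc, seed = 1, density = 0.4) {
  set.seed(seed)
  v <- matrix(stats::rexp(ng * nc, 2), ng, nc) *
    (matrix(stats::runif(ng * nc), ng, nc) < density)
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(ng)),
                      symbol = sprintf("g%04d", seq_len(ng)),
                      chromosome = "1", start = seq_len(ng),
                      stringsAsFactors = FALSE)
  cells <- data.frame(barcode = sprintf("c%04d", seq_len(nc)),
                      sample_id = "S1", patient_id = "P1", group = "GG",
                      stringsAsFactors = FALSE)
  norm_matrix(Matrix::Matrix(v, sparse = TRUE), genes, cells)
}

# tiny count matrix from an explicit dense matrix
toy_count_matrix <- function(counts, symbols = NULL, chromosome = "1",
                             group = "GG", labels = NULL) {
  ng <- nrow(counts); nc <- ncol(counts)
  symbols <- symbols %||% sprintf("g%03d", seq_len(ng))
  genes <- data.frame(gene_id = symbols, symbol = symbols,
                      chromosome = rep_len(chromosome, ng),
                      start = seq_len(ng) * 10, stringsAsFactors = FALSE)
  count_matrix(Matrix::Matrix(counts, sparse = TRUE), genes,
               sprintf("bc%03d", seq_len(nc)), "S1", "P1", group, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cohort sized for CNV/malignant evaluation: 6 patients x 300 cells on a
# 6000-gene panel (gene density commensurate with the 101-gene window)
cnv_fixture <- function() {
  memo_fixture("cnv", {
    cfg <- cohort_config(n_patients = 6, nlung_patients = 2,
                         n_cells_per_sample = 300, n_genes = 6000,
                         seed = 101)
    ch <- simulate_cohort(cfg)
    nm <- qc_normalize_cohort(ch$samples)
    list(config = cfg, cohort = ch, nm = nm)
  })
}

# cohort sized for meta-program evaluation: 2000-gene panel, 1000 variable
# genes for the NMF input
metaprogram_fixture <- function() {
  memo_fixture("mp", {
    cfg <- cohort_config(n_patients = 6, nlung_patients = 2,
                         n_cells_per_sample = 300, n_genes = 2000,
                         seed = 205)
    ch <- simulate_cohort(cfg)
    nm <- qc_normalize_cohort(ch$samples)
    kept <- nm$genes$gene_id
    pooled <- do.call(cbind, lapply(ch$samples, function(m) {
      m$counts[match(kept, m$genes$gene_id), , drop = FALSE]
    }))
    all_key <- unlist(lapply(ch$samples,
                             function(m) paste(m$sample_id, m$barcodes)))
    key <- paste(nm$cells$sample_id, nm$cells$barcode)
    pm <- count_matrix(pooled[, match(key, all_key), drop = FALSE],
                       nm$genes, key, "pooled", "pooled", "GG")
    hvg <- select_variable_genes(pm, 1000)
    list(config = cfg, cohort = ch, nm = nm, hvg = hvg)
  })
}

# QC fixture: 1000 cells with every violation class planted (8000-gene
# panel so the detected-gene ceiling can be exceeded)
qc_fixture <- function() {
  memo_fixture("qc", {
    cfg <- cohort_config(n_patients = 1, nlung_patients = 0,
                         n_cells_per_sample = 500, n_genes = 8000,
                         qc_contaminant_fractions = c(low_genes = 0.05,
                                                      high_genes = 0.03,
                                                      high_mito = 0.05,
                                                      high_umi = 0.02),
                         seed = 301)
    simulate_cohort(cfg)
  })
}
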