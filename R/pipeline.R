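# End-to-end orchestration: QC -> normalization -> label intake (or
# fallback clustering) -> per-patient CNV/malignant calling -> per-sample
# NMF meta-programs -> signature scores -> composition + mixed-model tests
# -> ligand-receptor communication. Each stage logs its input/output
# dimensions; the whole run is reproducible from config + seed.

#' QC, normalize and merge a set of samples
#'
#' Applies [filter_cells()] and [filter_genes()] per sample with the
#' config's thresholds, log-normalizes, restricts all samples to the
#' shared post-filter gene panel and merges into one multi-sample
#' [norm_matrix()]. Labels carried by the samples propagate to the merged
#' cell table.
#'
#' @param samples List of [count_matrix()].
#' @param config A [run_config()].
#' @return A merged [norm_matrix()], with attribute `qc_summary`.
#' @export
qc_normalize_cohort <- function(samples, config = run_config()) {
  qc_rows <- list(); norm_list <- list()
  for (m in samples) {
    fc <- filter_cells(m, config$min_genes, config$max_genes,
                       config$max_mito_frac, config$max_umis)
    fg <- filter_genes(fc, config$gene_min_cells)
    qc_rows[[m$sample_id]] <- cbind(sample_id = m$sample_id,
                                    attr(fc, "qc_summary"),
                                    genes_removed = nrow(fc$counts) -
                                      nrow(fg$counts))
    norm_list[[m$sample_id]] <- lognormalize(fg, config$scale_factor)
  }
  kept <- Reduce(intersect, lapply(norm_list, function(x) x$genes$gene_id))
  norm_list <- lapply(norm_list, function(nmx) {
    idx <- match(kept, nmx$genes$gene_id)
    norm_matrix(nmx$values[idx, , drop = FALSE],
                nmx$genes[idx, , drop = FALSE], nmx$cells, nmx$scale_factor)
  })
  nm <- merge_norm(norm_list)
  attr(nm, "qc_summary") <- do.call(rbind, c(qc_rows,
                                             make.row.names = FALSE))
  nm
}

#' Run the full pipeline
#'
#' Executes every stage on a set of samples and writes tabular outputs to
#' `outdir` (when given): `qc_summary.tsv`, `malignant_calls.tsv`,
#' `programs.tsv`, `metaprograms.tsv`, `signature_scores.tsv`,
#' `composition.tsv`, `tests.tsv`, `lmm.tsv`, `lr_results.tsv`.
#'
#' @param samples List of [count_matrix()], or a fixture directory path
#'   readable by [read_fixture()].
#' @param config A [run_config()].
#' @param gene_sets Optional list of [gene_set()] to score.
#' @param lr_pairs Optional list of [lr_pair()] to test.
#' @param marker_table Optional named list of marker genes, used for the
#'   doublet flag and for fallback annotation when samples carry no labels.
#' @param nmf_k_range Optional override of the NMF rank range.
#' @param outdir Optional output directory.
#' @return A `run_report`: list with per-stage results and a `log` of
#'   stage messages.
#' @export
run_pipeline <- function(samples, config = run_config(), gene_sets = NULL,
                         lr_pairs = NULL, marker_table = NULL,
                         nmf_k_range = NULL, outdir = NULL) {
  t_start <- as.numeric(Sys.time())
  if (is.character(samples)) samples <- read_fixture(samples)$samples
  log <- character()
  note <- function(...) log <<- c(log, stage_log(...))
  report <- list()

  # --- QC + normalization, per sample -------------------------------------
  t0 <- as.numeric(Sys.time())
  n_cells_in <- sum(vapply(samples, function(m) ncol(m$counts), integer(1)))
  nm <- qc_normalize_cohort(samples, config)
  report$qc_summary <- attr(nm, "qc_summary")
  kept <- nm$genes$gene_id
  note("qc_normalize", cells_in = n_cells_in, cells_out = ncol(nm$values),
       genes = nrow(nm$values), t0 = t0)

  # --- labels: supplied, or fallback clustering + marker annotation -------
  t0 <- as.numeric(Sys.time())
  have_labels <- !is.null(nm$cells$label)
  if (!have_labels) {
    if (is.null(marker_table)) {
      stop("stage labels: no labels supplied and no marker_table for fallback")
    }
    cl <- cluster_cells(nm, k = max(4L, length(marker_table)),
                        seed = derive_seed(config$seed, "cluster"))
    nm$cells$label <- annotate_clusters(nm, cl, marker_table)
  }
  if (!is.null(marker_table) && length(marker_table)) {
    doublet <- flag_doublets(nm, marker_table)
    report$doublet_flags <- data.frame(nm$cells[, c("sample_id", "barcode")],
                                       doublet = doublet)
    nm <- subset_cells(nm, !doublet)
    note("doublets", flagged = sum(doublet), retained = ncol(nm$values))
  }
  note("labels", cells = ncol(nm$values),
       types = length(unique(nm$cells$label)), t0 = t0)
  report$norm <- nm

  # --- variable genes (on pooled counts of retained cells) ----------------
  pooled_counts <- do.call(cbind, lapply(samples, function(m) {
    m$counts[match(kept, m$genes$gene_id), , drop = FALSE]
  }))
  keep_key <- paste(nm$cells$sample_id, nm$cells$barcode)
  all_key <- unlist(lapply(samples, function(m) paste(m$sample_id, m$barcodes)))
  pseudo <- count_matrix(pooled_counts[, match(keep_key, all_key),
                                       drop = FALSE],
                         nm$genes, keep_key, "pooled", "pooled", "GG")
  hvg <- select_variable_genes(pseudo, config$n_variable_genes)
  note("variable_genes", selected = length(hvg))

  # --- CNV / malignant calling per patient --------------------------------
  t0 <- as.numeric(Sys.time())
  calls <- call_malignant_cells(nm, window = config$cnv_window,
                                clip = config$cnv_clip,
                                top_frac = config$cnv_top_frac,
                                r_threshold = config$cnv_r_threshold)
  report$malignant_calls <- calls
  note("cnv_malignant", query_cells = nrow(calls),
       malignant = sum(calls$malignant), t0 = t0)

  # --- NMF meta-programs over malignant cells -----------------------------
  t0 <- as.numeric(Sys.time())
  mal_key <- paste(calls$sample_id, calls$barcode)[calls$malignant]
  mal_nm <- subset_cells(nm, paste(nm$cells$sample_id, nm$cells$barcode)
                         %in% mal_key)
  k_range <- nmf_k_range %||% seq(config$nmf_k_min, config$nmf_k_max)
  mp <- if (ncol(mal_nm$values) >= config$nmf_min_cells) {
    discover_metaprograms(mal_nm, genes_use = hvg, k_range = k_range,
                          top_n = config$nmf_top_n,
                          robust_overlap = config$nmf_robust_overlap,
                          core_frac = config$nmf_core_frac,
                          min_cells = config$nmf_min_cells,
                          seed = derive_seed(config$seed, "nmf"))
  } else {
    note("metaprograms", skipped = "too few malignant cells")
    NULL
  }
  report$metaprograms <- mp
  n_mp <- if (is.null(mp)) 0 else sum(vapply(mp[c("GG", "solid")], function(p)
    if (is.null(p)) 0L else length(p$metaprograms), integer(1)), na.rm = TRUE)
  note("metaprograms", meta_programs = n_mp, t0 = t0)

  # --- signature scores + mixed-model group tests -------------------------
  t0 <- as.numeric(Sys.time())
  lmm_rows <- list()
  if (!is.null(gene_sets) && length(gene_sets)) {
    scores <- score_named_sets(nm, gene_sets, config$sig_n_bins,
                               config$sig_n_background,
                               seed = derive_seed(config$seed, "signatures"))
    report$signature_scores <- cbind(nm$cells, scores)
    groups <- unique(nm$cells$group)
    pairs_ <- utils::combn(sort(groups), 2, simplify = FALSE)
    for (set_name in colnames(scores)) {
      for (gp in pairs_) {
        idx <- nm$cells$group %in% gp
        if (length(unique(nm$cells$patient_id[idx])) < 2) next
        fit <- fit_lmm(scores[idx, set_name], nm$cells$group[idx],
                       nm$cells$patient_id[idx])
        lmm_rows[[length(lmm_rows) + 1L]] <-
          cbind(score = set_name, comparison = paste(gp, collapse = "_vs_"),
                fit)
      }
    }
    report$lmm <- if (length(lmm_rows)) {
      do.call(rbind, c(lapply(lmm_rows, as.data.frame),
                       make.row.names = FALSE))
    } else NULL
    note("signatures", sets = ncol(scores), lmm_fits = length(lmm_rows),
         t0 = t0)
  }

  # --- composition + Wilcoxon/BH ------------------------------------------
  t0 <- as.numeric(Sys.time())
  sample_meta <- unique(nm$cells[, c("sample_id", "patient_id", "group")])
  comp <- composition_table(nm$cells, sample_meta)
  report$composition <- comp
  type_cols <- setdiff(colnames(comp), c("sample_id", "patient_id", "group"))
  tests <- list()
  for (tp in type_cols) {
    pr <- list()
    for (gp in utils::combn(sort(unique(comp$group)), 2, simplify = FALSE)) {
      x <- comp[comp$group == gp[1], tp]; y <- comp[comp$group == gp[2], tp]
      if (!length(x) || !length(y)) next
      wt <- wilcoxon_test(x, y)
      pr[[paste(gp, collapse = "_vs_")]] <- wt$p.value
      tests[[length(tests) + 1L]] <- data.frame(
        cell_type = tp, comparison = paste(gp, collapse = "_vs_"),
        statistic = wt$statistic, p = wt$p.value, method = wt$method,
        stringsAsFactors = FALSE)
    }
    # BH family: one cell type across its group comparisons
    if (length(pr)) {
      adj <- bh_adjust(unlist(pr))
      for (i in seq_along(adj)) {
        tests[[length(tests) - length(adj) + i]]$p_adj <- adj[i]
      }
    }
  }
  report$tests <- if (length(tests)) {
    do.call(rbind, c(tests, make.row.names = FALSE))
  } else NULL
  note("composition", samples = nrow(comp), types = length(type_cols), t0 = t0)

  # --- ligand-receptor communication --------------------------------------
  if (!is.null(lr_pairs) && length(lr_pairs)) {
    t0 <- as.numeric(Sys.time())
    lr <- lr_permutation_test(nm, nm$cells$label, lr_pairs,
                              n_perm = config$n_permutations,
                              hill_constant = config$hill_constant,
                              min_group_cells = config$min_group_cells,
                              seed = derive_seed(config$seed, "lr"))
    report$lr_results <- lr
    note("lr_comm", combinations = nrow(lr), t0 = t0)
  }

  note("done", stages = length(log), t0 = t_start)
  report$log <- log
  if (!is.null(outdir)) write_report(report, outdir)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report with stages:\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(report$qc_summary, "qc_summary.tsv")
  wt(report$malignant_calls, "malignant_calls.tsv")
  wt(report$signature_scores, "signature_scores.tsv")
  wt(report$composition, "composition.tsv")
  wt(report$tests, "tests.tsv")
  wt(report$lmm, "lmm.tsv")
  wt(report$lr_results, "lr_results.tsv")
  mp <- report$metaprograms
  if (!is.null(mp)) {
    rows <- list()
    for (grp in intersect(c("GG", "solid"), names(mp))) {
      pool <- mp[[grp]]
      for (i in seq_along(pool$metaprograms)) {
        m <- pool$metaprograms[[i]]
        rows[[length(rows) + 1L]] <- data.frame(
          pool = grp, metaprogram = paste0(grp, "_MP", i),
          members = paste(m$member_ids, collapse = ","),
          core_genes = paste(m$core_genes, collapse = ","),
          stringsAsFactors = FALSE)
      }
      if (!is.null(pool$tree)) {
        write_program_tree(pool$tree,
                           file.path(outdir, paste0("programs_", grp, ".nwk")))
      }
    }
    if (length(rows)) wt(do.call(rbind, rows), "metaprograms.tsv")
  }
  writeLines(report$log, file.path(outdir, "pipeline_log.txt"))
  invisible(outdir)
}
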