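# Reading and writing 10x-style MatrixMarket triplets and run configuration.

find_triplet_file <- function(directory, name) {
  for (cand in c(name, paste0(name, ".gz"))) {
    p <- file.path(directory, cand)
    if (file.exists(p)) return(p)
  }
  stop("missing ", name, "[.gz] in ", directory)
}

read_tsv_plain <- function(path, col_names) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  classes <- ifelse(col_names == "start", "numeric", "character")
  df <- tryCatch(
    utils::read.table(con, sep = "\t", header = FALSE, quote = "",
                      stringsAsFactors = FALSE, colClasses = classes,
                      col.names = col_names, comment.char = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        as.data.frame(stats::setNames(replicate(length(col_names),
                                                character(0),
                                                simplify = FALSE), col_names))
      } else stop(e)
    })
  df
}

#' Read a 10x-style MatrixMarket triplet
#'
#' Expects `matrix.mtx`, `genes.tsv` (gene id, symbol, chromosome, start)
#' and `barcodes.tsv` in `directory`, each optionally gzipped. MTX indices
#' are 1-based on disk and mapped to the internal representation. Sample
#' metadata is taken from `sample_meta.tsv` in the directory when present;
#' explicit arguments override it.
#'
#' @param directory Path containing the triplet.
#' @param sample_id,patient_id,group Optional metadata overrides.
#' @return A [count_matrix()].
#' @export
read_mtx_triplet <- function(directory, sample_id = NULL, patient_id = NULL,
                             group = NULL) {
  mtx_path <- find_triplet_file(directory, "matrix.mtx")
  con <- if (grepl("\\.gz$", mtx_path)) gzfile(mtx_path) else mtx_path
  mat <- methods::as(methods::as(Matrix::readMM(con), "generalMatrix"),
                     "CsparseMatrix")
  genes <- read_tsv_plain(find_triplet_file(directory, "genes.tsv"),
                          c("gene_id", "symbol", "chromosome", "start"))
  genes$start <- as.numeric(genes$start)
  barcodes <- read_tsv_plain(find_triplet_file(directory, "barcodes.tsv"),
                             "barcode")$barcode
  if (nrow(genes) != nrow(mat)) {
    stop("genes.tsv has ", nrow(genes), " rows but matrix.mtx header says ",
         nrow(mat), " genes (", directory, ")")
  }
  if (length(barcodes) != ncol(mat)) {
    stop("barcodes.tsv has ", length(barcodes), " rows but matrix.mtx ",
         "header says ", ncol(mat), " cells (", directory, ")")
  }
  meta_path <- file.path(directory, "sample_meta.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else NULL
  labels_path <- file.path(directory, "labels.tsv")
  labels <- if (file.exists(labels_path)) {
    read_tsv_plain(labels_path, "label")$label
  } else NULL
  count_matrix(mat, genes, barcodes,
               sample_id %||% meta$sample_id %||% basename(directory),
               patient_id %||% meta$patient_id %||% basename(directory),
               group %||% meta$group %||% "GG",
               labels = labels)
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' Inverse of [read_mtx_triplet()]: writes `matrix.mtx` (coordinate integer,
#' 1-based), `genes.tsv`, `barcodes.tsv`, `sample_meta.tsv` and, when the
#' matrix carries labels, `labels.tsv`.
#'
#' @param m A [count_matrix()].
#' @param directory Target directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_mtx_triplet <- function(m, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  x <- m$counts
  dimnames(x) <- NULL
  Matrix::writeMM(x, file.path(directory, "matrix.mtx"))
  utils::write.table(m$genes[, c("gene_id", "symbol", "chromosome", "start")],
                     file.path(directory, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(m$barcodes, file.path(directory, "barcodes.tsv"))
  utils::write.table(data.frame(sample_id = m$sample_id,
                                patient_id = m$patient_id, group = m$group),
                     file.path(directory, "sample_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(m$labels)) {
    writeLines(m$labels, file.path(directory, "labels.tsv"))
  }
  invisible(directory)
}

#' Read a cohort fixture directory
#'
#' Reads every sample listed in `samples.tsv` (as written by
#' [write_fixture()]) plus ground-truth tables when present.
#'
#' @param directory Fixture root.
#' @return List with `samples`, `truth`, `gene_truth` (the latter two NULL
#'   when absent).
#' @export
read_fixture <- function(directory) {
  meta <- utils::read.table(file.path(directory, "samples.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    read_mtx_triplet(file.path(directory, meta$sample_id[i]),
                     sample_id = meta$sample_id[i],
                     patient_id = meta$patient_id[i], group = meta$group[i])
  })
  names(samples) <- meta$sample_id
  read_opt <- function(name) {
    p <- file.path(directory, name)
    if (file.exists(p)) {
      utils::read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    } else NULL
  }
  list(samples = samples, truth = read_opt("ground_truth.tsv"),
       gene_truth = read_opt("gene_truth.tsv"))
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its standard defaults: QC
#' thresholds (200/6000 detected genes, 15% mitochondrial UMIs, 60,000
#' UMIs, genes in at least 5 cells), log-normalization scale factor 10000,
#' 2000 variable genes, CNV estimation (window 101 genes, clip 3, top 5%
#' reference cells, Pearson r threshold 0.3), NMF meta-programs (k 6..9,
#' top 50 genes, 35-gene cross-rank overlap, 25% core-gene fraction),
#' signature scoring (25 bins, 100 background genes), and permutation
#' count for the communication test.
#'
#' @param ... Overrides of any default field.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_genes = 200, max_genes = 6000, max_mito_frac = 0.15,
    max_umis = 60000, gene_min_cells = 5,
    scale_factor = 10000, n_variable_genes = 2000,
    cnv_window = 101, cnv_clip = 3, cnv_top_frac = 0.05, cnv_r_threshold = 0.3,
    nmf_k_min = 6, nmf_k_max = 9, nmf_top_n = 50, nmf_robust_overlap = 35,
    nmf_core_frac = 0.25, nmf_min_cells = 20,
    sig_n_bins = 25, sig_n_background = 100,
    n_permutations = 999, hill_constant = 0.5, min_group_cells = 10,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$min_genes > 0, cfg$max_genes >= cfg$min_genes,
            cfg$max_mito_frac > 0, cfg$max_umis > 0,
            cfg$cnv_top_frac > 0, cfg$cnv_top_frac < 1,
            cfg$nmf_robust_overlap <= cfg$nmf_top_n,
            cfg$scale_factor > 0)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Flat keys mirroring the [run_config()] field names; every default is
#' overridable from file.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A `run_config` to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
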