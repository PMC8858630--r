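# Synthetic multi-patient cohort generator with planted ground truth.
#
# Emulates a 3-group lung cohort (normal lung, ground-glass and solid tumour
# components, GG/solid paired within patient) with: cell types whose
# abundance shifts between groups, chromosome-scale CNV segments carried by
# malignant cells, shared cross-sample expression programs active in a
# subset of malignant cells, additive group-level shifts on signature gene
# sets, and planted low-quality cells that each trip one QC rule.

# Run expr under a temporary seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

default_groups_per_patient <- function(n_patients, nlung_patients) {
  lapply(seq_len(n_patients), function(i) {
    if (i <= nlung_patients) c("nLung", "GG", "solid") else c("GG", "solid")
  })
}

build_gene_panel <- function(n_genes, n_chromosomes, n_mito_genes) {
  stopifnot(n_genes > n_mito_genes)
  n_nuc <- n_genes - n_mito_genes
  chrom <- as.character(rep(seq_len(n_chromosomes), length.out = n_nuc)[
    order(rep(seq_len(n_chromosomes), length.out = n_nuc))])
  # blockwise assignment, near-equal chromosome sizes
  sizes <- tabulate(rep(seq_len(n_chromosomes), length.out = n_nuc))
  chrom <- rep(as.character(seq_len(n_chromosomes)), times = sizes)
  start <- unlist(lapply(sizes, function(s) seq_len(s) * 10000L))
  ids <- sprintf("G%05d", seq_len(n_nuc))
  panel <- data.frame(gene_id = c(ids, sprintf("MT-%d", seq_len(n_mito_genes))),
                      symbol = c(ids, sprintf("MT-%d", seq_len(n_mito_genes))),
                      chromosome = c(chrom, rep("MT", n_mito_genes)),
                      start = c(start, seq_len(n_mito_genes) * 1000L),
                      stringsAsFactors = FALSE)
  panel
}

default_cell_type_spec <- function(panel, markers_per_type = 8,
                                   marker_boost = 2.5, baseline_sdlog = 1.5) {
  types <- c("Epithelial", "Malignant", "T", "Myeloid", "Fibroblast",
             "Endothelial")
  weights <- list(
    nLung = c(Epithelial = 0.30, Malignant = 0.00, T = 0.30, Myeloid = 0.20,
              Fibroblast = 0.10, Endothelial = 0.10),
    GG    = c(Epithelial = 0.15, Malignant = 0.20, T = 0.30, Myeloid = 0.20,
              Fibroblast = 0.08, Endothelial = 0.07),
    solid = c(Epithelial = 0.10, Malignant = 0.35, T = 0.20, Myeloid = 0.20,
              Fibroblast = 0.08, Endothelial = 0.07))
  nuclear <- panel$chromosome != "MT"
  base_log <- stats::rnorm(sum(nuclear), 0, baseline_sdlog)
  # markers drawn from chromosomes 2 and 9 so default CNV segments (1, 3,
  # 5) and program gene pools stay free of type-specific baseline
  # differences; scattered along the chromosomes (as real marker genes
  # are), so no window-scale expression block mimics a CNV segment
  pool <- which(panel$chromosome[nuclear] %in% c("2", "9"))
  n_mark <- markers_per_type * length(types)
  stopifnot(length(pool) >= n_mark)
  scattered <- pool[round(seq(1, length(pool), length.out = n_mark))]
  # round-robin assignment interleaves the types along the genome
  marker_rows <- matrix(scattered, nrow = length(types), byrow = FALSE)
  marker_rows <- t(marker_rows)
  spec <- lapply(seq_along(types), function(i) {
    lv <- base_log
    # canonical markers are near-exclusive: silenced in foreign types,
    # boosted in their own
    lv[as.vector(marker_rows)] <- lv[as.vector(marker_rows)] - 3
    lv[marker_rows[, i]] <- lv[marker_rows[, i]] + 3 + marker_boost
    list(type = types[i],
         markers = panel$gene_id[nuclear][marker_rows[, i]],
         log_baseline = lv)
  })
  names(spec) <- types
  list(types = spec, weights = weights)
}

default_cnv_spec <- function() {
  list(list(chromosome = "1", fold = 2.0, carrier = "Malignant"),
       list(chromosome = "3", fold = 2.0, carrier = "Malignant"),
       list(chromosome = "5", fold = 0.5, carrier = "Malignant"))
}

default_program_spec <- function(panel, n_programs = 3, genes_per_program = 50,
                                 on_prob = 0.3, amplitude = 2.0) {
  pool <- panel$gene_id[panel$chromosome %in% c("4", "6", "8")]
  n_need <- n_programs * genes_per_program
  stopifnot(length(pool) >= n_need)
  # genes interleaved along the genome (program i takes every n_programs-th
  # slot), so no program forms a contiguous block mimicking a CNV segment
  slots <- pool[round(seq(1, length(pool), length.out = n_need))]
  lapply(seq_len(n_programs), function(i) {
    list(name = paste0("program", i),
         genes = slots[seq(i, n_need, by = n_programs)],
         on_prob = on_prob, amplitude = amplitude)
  })
}

default_signature_shift_spec <- function(panel, n_genes_set = 40) {
  pool <- panel$gene_id[panel$chromosome == "7"]
  genes <- pool[round(seq(1, length(pool),
                          length.out = min(n_genes_set, length(pool))))]
  list(list(name = "stress_response", genes = genes, group = "GG", shift = 0.25),
       list(name = "stress_response", genes = genes, group = "solid", shift = 0.5))
}

#' Configuration for the synthetic cohort generator
#'
#' Builds a fully materialized cohort configuration. Defaults mirror the
#' study design the pipeline targets: 12 patients each contributing a paired
#' GG and solid tumour sample, with normal-lung samples for the first 5
#' patients; malignant cells carry three chromosome-scale CNV segments
#' (two amplifications at fold 2, one deletion at fold 0.5) and three shared
#' 50-gene expression programs; one signature gene set is shifted upward in
#' the tumour groups; a small fraction of cells per sample is planted to
#' violate each QC rule.
#'
#' All derived quantities (gene panel, baseline expression, marker
#' assignments) are generated deterministically from `seed`; the caller's
#' RNG state is untouched.
#'
#' @param n_patients Number of patients (each with a GG and a solid sample).
#' @param nlung_patients How many patients also contribute a normal-lung
#'   sample (the first `nlung_patients`).
#' @param n_cells_per_sample Cells per sample.
#' @param n_genes Total genes in the panel, including `n_mito_genes`
#'   mitochondrial genes (symbols prefixed "MT-").
#' @param n_chromosomes Autosomes the nuclear genes are split over.
#' @param n_mito_genes Mitochondrial genes.
#' @param cell_type_spec,cnv_spec,program_spec,signature_shift_spec
#'   Optional overrides of the planted structure; see the default builders
#'   in the package source for their shapes.
#' @param qc_contaminant_fractions Named fractions of cells per sample
#'   planted to violate each QC rule
#'   (`low_genes`, `high_genes`, `high_mito`, `high_umi`). Planting
#'   `high_genes` requires `n_genes` above the detected-gene ceiling of
#'   6000, so its default is 0 for the 2000-gene default panel.
#' @param libsize_lognormal_params Named `meanlog`/`sdlog` of the per-cell
#'   library size distribution.
#' @param mito_frac_mean Mean fraction of each cell's library allocated to
#'   mitochondrial genes.
#' @param nb_dispersion Negative binomial size parameter shared by all genes.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   byte-identically.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 12,
                          nlung_patients = min(5, n_patients),
                          n_cells_per_sample = 200, n_genes = 2000,
                          n_chromosomes = 10, n_mito_genes = 13,
                          cell_type_spec = NULL, cnv_spec = NULL,
                          program_spec = NULL, signature_shift_spec = NULL,
                          qc_contaminant_fractions = c(low_genes = 0.02,
                                                       high_genes = 0,
                                                       high_mito = 0.02,
                                                       high_umi = 0.01),
                          libsize_lognormal_params = c(meanlog = log(2500),
                                                       sdlog = 0.3),
                          mito_frac_mean = 0.05, nb_dispersion = 2,
                          seed = 1L) {
  stopifnot(n_patients >= 1, nlung_patients >= 0, nlung_patients <= n_patients,
            n_cells_per_sample >= 1, n_genes >= 100, n_chromosomes >= 1,
            nb_dispersion > 0, mito_frac_mean > 0, mito_frac_mean < 1)
  qcf <- c(low_genes = 0, high_genes = 0, high_mito = 0, high_umi = 0)
  qcf[names(qc_contaminant_fractions)] <- qc_contaminant_fractions
  stopifnot(all(qcf >= 0), sum(qcf) < 1)
  if (qcf[["high_genes"]] > 0 && n_genes <= 6200) {
    stop("planting high_genes violations needs n_genes > 6200")
  }
  panel <- build_gene_panel(n_genes, n_chromosomes, n_mito_genes)
  cfg <- with_preserved_rng(derive_seed(seed, "cohort_config"), {
    cts <- cell_type_spec %||% default_cell_type_spec(panel)
    list(cell_type_spec = cts)
  })
  cnv_spec <- cnv_spec %||% default_cnv_spec()
  program_spec <- program_spec %||% default_program_spec(panel)
  signature_shift_spec <- signature_shift_spec %||%
    default_signature_shift_spec(panel)
  for (pr in program_spec) {
    if (anyDuplicated(pr$genes)) stop("program gene list has duplicates: ", pr$name)
    if (!all(pr$genes %in% panel$gene_id)) {
      stop("program ", pr$name, " references unknown genes")
    }
  }
  for (sp in cnv_spec) stopifnot(sp$fold > 0)
  for (g in names(cfg$cell_type_spec$weights)) {
    stopifnot(abs(sum(cfg$cell_type_spec$weights[[g]]) - 1) < 1e-9)
  }
  structure(list(
    n_patients = n_patients, nlung_patients = nlung_patients,
    groups_per_patient = default_groups_per_patient(n_patients, nlung_patients),
    n_cells_per_sample = n_cells_per_sample, n_genes = n_genes,
    n_chromosomes = n_chromosomes, n_mito_genes = n_mito_genes,
    gene_panel = panel, cell_type_spec = cfg$cell_type_spec,
    cnv_spec = cnv_spec, program_spec = program_spec,
    signature_shift_spec = signature_shift_spec,
    qc_contaminant_fractions = qcf,
    libsize_lognormal_params = libsize_lognormal_params,
    mito_frac_mean = mito_frac_mean, nb_dispersion = nb_dispersion,
    seed = as.integer(seed)), class = "cohort_config")
}

# Per-cell expected expression on the simplex: nuclear genes get
# (1 - mito_frac) x softmax(log baseline + planted log-fold terms), the
# mitochondrial genes share mito_frac uniformly.
cell_probability <- function(config, type, malignant, program_activity,
                             group, mito_frac) {
  panel <- config$gene_panel
  nuclear <- panel$chromosome != "MT"
  eta <- config$cell_type_spec$types[[type]]$log_baseline
  if (malignant) {
    for (seg in config$cnv_spec) {
      on_seg <- panel$chromosome[nuclear] == seg$chromosome
      eta[on_seg] <- eta[on_seg] + log(seg$fold)
    }
  }
  if (length(config$program_spec)) {
    for (i in seq_along(config$program_spec)) {
      a <- program_activity[i]
      if (a > 0) {
        pr <- config$program_spec[[i]]
        rows <- match(pr$genes, panel$gene_id[nuclear])
        eta[rows] <- eta[rows] + a
      }
    }
  }
  for (sh in config$signature_shift_spec) {
    if (identical(sh$group, group)) {
      rows <- match(sh$genes, panel$gene_id[nuclear])
      rows <- rows[!is.na(rows)]
      eta[rows] <- eta[rows] + sh$shift
    }
  }
  w <- exp(eta - max(eta))
  p <- numeric(nrow(panel))
  p[nuclear] <- (1 - mito_frac) * w / sum(w)
  p[!nuclear] <- mito_frac / sum(!nuclear)
  p
}

# Deterministic post-draw corrections guaranteeing that a "none" cell
# passes every QC rule (rare fixes; documented in the methods vignette).
enforce_clean <- function(counts, mito_idx, min_genes = 200, max_genes = 6000,
                          max_mito = 0.15, max_umis = 60000) {
  nuc_idx <- setdiff(seq_along(counts), mito_idx)
  if (sum(counts) > max_umis) {
    keep <- counts > 0
    counts[keep] <- as.vector(stats::rmultinom(1, 50000,
                                               counts[keep] / sum(counts)))
  }
  detected <- sum(counts > 0)
  if (detected < min_genes) {
    zeros <- nuc_idx[counts[nuc_idx] == 0]
    add <- utils::head(zeros, min_genes - detected)
    counts[add] <- 1L
  } else if (detected > max_genes) {
    pos <- which(counts > 0)
    drop <- pos[order(counts[pos])][seq_len(detected - max_genes)]
    counts[drop] <- 0L
  }
  mt <- sum(counts[mito_idx]); nm <- sum(counts) - mt
  if (nm > 0 && mt / (mt + nm) > max_mito) {
    target <- floor(0.12 / 0.88 * nm)
    counts[mito_idx] <- floor(counts[mito_idx] * target / max(mt, 1))
  }
  counts
}

#' Simulate a synthetic multi-patient cohort
#'
#' Draws one UMI count matrix per (patient, group) sample under the
#' configured generative model: per cell, a type from the group's abundance
#' weights, a log-normal library size, and negative-binomial counts with
#' mean `libsize x p`, where `p` places the configured mitochondrial
#' fraction on "MT-" genes and distributes the rest as the softmax of the
#' type's log baseline plus planted CNV log-folds (malignant cells),
#' program activities, and group-level signature shifts. Cells planted as
#' QC violators are constructed to trip exactly their violation rule;
#' clean cells are guaranteed to pass every rule.
#'
#' @param config A [cohort_config()].
#' @return List with `samples` (list of [count_matrix()]), `truth`
#'   (per-cell data frame: sample, barcode, type, malignant flag, program
#'   activities, QC class), and `gene_truth` (per-gene CNV/program
#'   membership).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  panel <- config$gene_panel
  mito_idx <- which(panel$chromosome == "MT")
  carriers <- unique(vapply(config$cnv_spec, `[[`, "", "carrier"))
  n_cells <- config$n_cells_per_sample
  qcf <- config$qc_contaminant_fractions
  ll <- config$libsize_lognormal_params
  conc <- 30
  samples <- list(); truth <- list()
  for (pat in seq_len(config$n_patients)) {
    patient_id <- sprintf("P%02d", pat)
    for (group in config$groups_per_patient[[pat]]) {
      sample_id <- paste0(patient_id, "_", group)
      w <- config$cell_type_spec$weights[[group]]
      types <- sample(names(w), n_cells, replace = TRUE, prob = w)
      malignant <- types %in% carriers
      libsize <- stats::rlnorm(n_cells, ll[["meanlog"]], ll[["sdlog"]])
      mito_frac <- stats::rbeta(n_cells, config$mito_frac_mean * conc,
                                (1 - config$mito_frac_mean) * conc)
      n_prog <- length(config$program_spec)
      activity <- matrix(0, n_cells, max(n_prog, 1))
      if (n_prog) {
        for (i in seq_len(n_prog)) {
          pr <- config$program_spec[[i]]
          on <- malignant & (stats::runif(n_cells) < pr$on_prob)
          activity[on, i] <- pr$amplitude * stats::runif(sum(on), 0.8, 1.2)
        }
      }
      # planted QC violators: disjoint random cell subsets per class
      qc_class <- rep("none", n_cells)
      n_violate <- round(qcf * n_cells)
      pool <- sample.int(n_cells)
      off <- 0
      for (cls in names(n_violate)) {
        k <- n_violate[[cls]]
        if (k > 0) {
          qc_class[pool[off + seq_len(k)]] <- cls
          off <- off + k
        }
      }
      counts <- matrix(0L, nrow(panel), n_cells)
      nuc_idx <- setdiff(seq_len(nrow(panel)), mito_idx)
      for (c in seq_len(n_cells)) {
        p <- cell_probability(config, types[c], malignant[c], activity[c, ],
                              group, mito_frac[c])
        cls <- qc_class[c]
        if (cls == "low_genes") {
          # support capped at 150 nuclear genes: detected < 200 by construction
          support <- sample(nuc_idx, 150, prob = p[nuc_idx])
          cnt <- numeric(nrow(panel))
          cnt[support] <- stats::rmultinom(1, 600, p[support])
          counts[, c] <- as.integer(cnt)
        } else if (cls == "high_genes") {
          hit <- sample(nuc_idx, 6500)
          cnt <- numeric(nrow(panel))
          cnt[hit] <- 1
          cnt[nuc_idx] <- cnt[nuc_idx] +
            as.vector(stats::rmultinom(1, 5000, p[nuc_idx]))
          counts[, c] <- as.integer(cnt)
        } else if (cls == "high_umi") {
          support <- sample(nuc_idx, min(3000, length(nuc_idx)), prob = p[nuc_idx])
          cnt <- numeric(nrow(panel))
          cnt[support] <- stats::rmultinom(1, 70001, p[support])
          counts[, c] <- as.integer(cnt)
        } else if (cls == "high_mito") {
          cnt <- stats::rnbinom(nrow(panel), mu = libsize[c] * p,
                                size = config$nb_dispersion)
          nm_total <- sum(cnt[nuc_idx])
          mt_total <- ceiling(nm_total / 3) + 1  # fraction > 0.25 > 0.15
          cnt[mito_idx] <- as.vector(stats::rmultinom(1, mt_total,
                                                      rep(1, length(mito_idx))))
          cnt <- enforce_clean_partial(cnt, nuc_idx)
          counts[, c] <- as.integer(cnt)
        } else {
          cnt <- stats::rnbinom(nrow(panel), mu = libsize[c] * p,
                                size = config$nb_dispersion)
          counts[, c] <- as.integer(enforce_clean(cnt, mito_idx))
        }
      }
      barcodes <- sprintf("%s_C%04d", sample_id, seq_len(n_cells))
      samples[[sample_id]] <- count_matrix(
        Matrix::Matrix(counts, sparse = TRUE), panel, barcodes,
        sample_id, patient_id, group, labels = types)
      tr <- data.frame(sample_id = sample_id, barcode = barcodes,
                       patient_id = patient_id, group = group,
                       cell_type = types, malignant = malignant,
                       qc_class = qc_class, stringsAsFactors = FALSE)
      if (n_prog) {
        colnames(activity) <- vapply(config$program_spec, `[[`, "", "name")
        tr <- cbind(tr, as.data.frame(activity))
      }
      truth[[sample_id]] <- tr
    }
  }
  gene_truth <- data.frame(gene_id = panel$gene_id, cnv_segment = NA_character_,
                           cnv_fold = 1, program = NA_character_,
                           stringsAsFactors = FALSE)
  for (seg in config$cnv_spec) {
    on_seg <- panel$chromosome == seg$chromosome
    gene_truth$cnv_segment[on_seg] <- paste0("chr", seg$chromosome)
    gene_truth$cnv_fold[on_seg] <- seg$fold
  }
  for (pr in config$program_spec) {
    gene_truth$program[match(pr$genes, gene_truth$gene_id)] <- pr$name
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(samples = samples, truth = truth, gene_truth = gene_truth)
}

# For planted high-mito cells: keep the *other* metrics in range so the
# recorded violation class is the rule that removes the cell.
enforce_clean_partial <- function(counts, nuc_idx, min_genes = 200,
                                  max_genes = 6000, max_umis = 60000) {
  detected <- sum(counts > 0)
  if (detected < min_genes) {
    zeros <- nuc_idx[counts[nuc_idx] == 0]
    counts[utils::head(zeros, min_genes - detected)] <- 1
  }
  counts
}

#' Write a cohort as a 10x-style fixture
#'
#' One directory per sample holding `matrix.mtx` (MatrixMarket coordinate
#' integer, 1-based indices), `genes.tsv`, `barcodes.tsv` and
#' `sample_meta.tsv`; plus cohort-level `samples.tsv`, `ground_truth.tsv`
#' and `gene_truth.tsv`. Round-trips losslessly through
#' [read_mtx_triplet()].
#'
#' @param cohort Result of [simulate_cohort()] (or a bare list of
#'   [count_matrix()] in `$samples`).
#' @param directory Target directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (m in cohort$samples) {
    d <- file.path(directory, m$sample_id)
    write_mtx_triplet(m, d)
    meta[[m$sample_id]] <- data.frame(sample_id = m$sample_id,
                                      patient_id = m$patient_id,
                                      group = m$group, stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, meta), file.path(directory, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.table(cohort$truth, file.path(directory, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$gene_truth)) {
    utils::write.table(cohort$gene_truth, file.path(directory, "gene_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(directory)
}
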