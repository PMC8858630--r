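mk_program <- function(genes, k, sample_id = "S1", factor_index = 1L) {
  structure(list(sample_id = sample_id, k = k, factor_index = factor_index,
                 genes = genes, scores = rev(seq_along(genes))),
            class = "expression_program")
}

gene_ids <- function(i) sprintf("G%03d", i)

test_that("NMF input preparation z-scores, drops constants and clips negatives", {
  set.seed(2)
  v <- matrix(rexp(30 * 25), 30, 25)
  v[5, ] <- 1                       # constant gene
  nm <- rand_norm_matrix(30, 25, seed = 2)
  nm$values <- Matrix::Matrix(v, sparse = TRUE)
  x <- prepare_nmf_matrix(nm, min_cells = 10)
  expect_equal(nrow(x), 29)         # constant dropped
  expect_true(all(x >= 0))
  # entries below the gene mean are zeroed
  g <- as.matrix(nm$values)[1, ]
  expect_equal(unname(x[1, g < mean(g)]), rep(0, sum(g < mean(g))))
  expect_error(prepare_nmf_matrix(nm, min_cells = 26), "cell floor")
})

test_that("NMF solves exact low-rank cases and is deterministic", {
  set.seed(3)
  x <- outer(runif(40) + 0.1, runif(15) + 0.1)
  rownames(x) <- gene_ids(1:40)
  f <- run_nmf(x, 1)
  expect_lt(f$error, 1e-6)
  f2 <- run_nmf(x, 1)
  expect_identical(f$W, f2$W)
  expect_identical(f$H, f2$H)
})

test_that("NMF recovers a planted two-block structure", {
  set.seed(4)
  x <- matrix(0.01, 40, 20)
  x[1:20, 1:10] <- x[1:20, 1:10] + 1
  x[21:40, 11:20] <- x[21:40, 11:20] + 1
  x <- x * matrix(runif(800, 0.7, 1.3), 40)
  rownames(x) <- gene_ids(1:40)
  f <- run_nmf(x, 2)
  progs <- extract_programs(f$W, 2, "S", top_n = 20)
  blocks <- list(gene_ids(1:20), gene_ids(21:40))
  jac <- sapply(progs, function(p) {
    max(sapply(blocks, function(b)
      length(intersect(p$genes, b)) / length(union(p$genes, b))))
  })
  expect_true(all(jac >= 0.9))
})

test_that("programs take the top-n loadings with lexicographic tie-break", {
  W <- cbind(c(3, 1, 2, 2, 0.5))
  rownames(W) <- c("Gb", "Gd", "Gc", "Ga", "Ge")
  p <- extract_programs(W, 1, "S", top_n = 3)[[1]]
  # loadings: Gb=3 first; tie at 2 between Gc and Ga -> Ga wins
  expect_equal(p$genes, c("Gb", "Ga", "Gc"))
  p_all <- extract_programs(W, 1, "S", top_n = 5)[[1]]
  expect_equal(p_all$genes, c("Gb", "Ga", "Gc", "Gd", "Ge"))
})

test_that("the robustness rule needs 35 shared genes at a different rank", {
  a <- mk_program(gene_ids(1:50), k = 6)
  b35 <- mk_program(gene_ids(c(1:35, 101:115)), k = 7)
  expect_length(robust_programs(list(a, b35)), 2)   # both certified
  b34 <- mk_program(gene_ids(c(1:34, 101:116)), k = 7)
  expect_length(robust_programs(list(a, b34)), 0)   # 34 genes: below
  same_k <- mk_program(gene_ids(1:50), k = 6, factor_index = 2L)
  expect_length(robust_programs(list(a, same_k)), 0) # same rank: no partner
})

test_that("robustness certification is symmetric", {
  set.seed(9)
  progs <- lapply(1:6, function(i) {
    mk_program(gene_ids(sample(200, 50)), k = sample(6:9, 1),
               factor_index = i)
  })
  kept <- robust_programs(progs, robust_overlap = 10)
  ids <- vapply(kept, function(p) p$factor_index, 0L)
  # every kept program has a kept partner at another k sharing >= 10 genes
  for (p in kept) {
    partners <- Filter(function(q) q$k != p$k &&
                         length(intersect(p$genes, q$genes)) >= 10, kept)
    expect_gte(length(partners), 1)
  }
})

test_that("program clustering groups by overlap distance", {
  a <- mk_program(gene_ids(1:50), 6, "S1")
  b <- mk_program(gene_ids(1:50), 7, "S2")
  c_ <- mk_program(gene_ids(101:150), 6, "S3")
  res <- cluster_programs(list(a, b, c_), top_n = 50, cut_height = 15)
  expect_length(res$metaprograms, 1)          # {a, b}; c alone spans 1 sample
  expect_setequal(res$metaprograms[[1]]$member_ids,
                  c(psnpipe:::program_id(a), psnpipe:::program_id(b)))
  # input order does not change the membership
  res2 <- cluster_programs(list(c_, b, a), top_n = 50, cut_height = 15)
  expect_setequal(res2$metaprograms[[1]]$member_ids,
                  res$metaprograms[[1]]$member_ids)
  # two identical programs cluster at any positive cut
  res3 <- cluster_programs(list(a, b), top_n = 50, cut_height = 1)
  expect_length(res3$metaprograms, 1)
})

test_that("core genes need 25% membership spanning two samples", {
  members <- c(
    lapply(1:4, function(i) mk_program(gene_ids(1:50), 5 + i, "S1", i)),
    lapply(1:4, function(i) mk_program(gene_ids(c(1:40, 61:70)), 5 + i,
                                       "S2", i)))
  mp <- structure(list(members = members), class = "meta_program")
  core <- core_genes(mp, 0.25)
  expect_true(all(gene_ids(1:40) %in% core))       # in all 8 programs
  # genes 61:70 sit in 4/8 programs but only in sample S2 -> excluded
  expect_false(any(gene_ids(61:70) %in% core))
  # a gene in 1 of 8 programs (12.5%) is below ceiling(0.25 * 8) = 2
  members2 <- c(members[1:7],
                list(mk_program(gene_ids(c(1:49, 99)), 9, "S2", 4)))
  mp2 <- structure(list(members = members2), class = "meta_program")
  expect_false(gene_ids(99) %in% core_genes(mp2, 0.25))
})

test_that("planted cross-sample programs are recovered as meta-programs", {
  fx <- metaprogram_fixture()
  mal <- subset_cells(fx$nm, fx$nm$cells$label == "Malignant")
  res <- discover_metaprograms(mal, genes_use = fx$hvg, k_range = 4:6,
                               seed = 17)
  planted <- lapply(fx$config$program_spec, `[[`, "genes")
  mps <- c(res$GG$metaprograms, res$solid$metaprograms)
  expect_gte(length(mps), 3)
  best <- vapply(planted, function(g) {
    max(vapply(mps, function(mp) {
      length(intersect(mp$core_genes, g)) / length(union(mp$core_genes, g))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(best >= 0.5))
})
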