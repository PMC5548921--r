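toy_counts <- function() {
  m <- matrix(c(10L, 20L, 10L, 20L), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  m
}

test_that("TSV and MTX count round trips are lossless", {
  sim <- simulate_counts(count_sim_spec(n_genes = 40, n_cells_a = 3,
                                        n_cells_b = 4, seed = 2))
  tsv <- file.path(withr::local_tempdir(), "counts.tsv")
  write_counts(sim$counts, tsv)
  expect_identical(read_counts(tsv), sim$counts)

  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "matrix.mtx")
  write_counts(sim$counts, mtx)
  back <- read_counts(mtx)
  expect_identical(back, sim$counts)
})

test_that("malformed count files are rejected with the offender named", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.tsv")
  writeLines(c("gene_id\tc1\tc2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(read_counts(f), "duplicate gene_id.*g1")
  writeLines(c("gene_id\tc1\tc2", "g1\t1\t2", "g2\t-3\t4"), f)
  expect_error(read_counts(f), "non-negative.*g2")
  writeLines(c("gene_id\tc1\tc2", "g1\t1.5\t2", "g2\t3\t4"), f)
  expect_error(read_counts(f), "integers.*g1")
})

test_that("all-zero genes are dropped and only those", {
  sim <- simulate_counts(count_sim_spec(n_genes = 200, seed = 6))
  m <- sim$counts
  m[sample(nrow(m), 7), ] <- 0L  # plant empty rows
  k <- sum(rowSums(m) == 0)
  expect_gte(k, 7)
  kept <- drop_all_zero_genes(m)
  expect_equal(nrow(kept), 200 - k)
  expect_true(all(rowSums(kept) > 0))
  expect_equal(attr(kept, "n_retained"), 200 - k)
  # idempotent when nothing to drop
  expect_equal(nrow(drop_all_zero_genes(kept)), nrow(kept))
})

test_that("size factors solve the hand-computable cases", {
  expect_equal(unname(size_factors(toy_counts())),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  m <- matrix(rep(c(5L, 9L, 30L), 4), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  expect_equal(unname(size_factors(m)), rep(1, 4))
})

test_that("size factors are gene-order invariant and scale equivariant", {
  sim <- simulate_counts(count_sim_spec(n_genes = 300, dropout_prob = 0,
                                        seed = 9))
  m <- sim$counts
  sf <- size_factors(m)
  perm <- sample(nrow(m))
  expect_equal(size_factors(m[perm, ]), sf)

  m3 <- m
  m3[, 4] <- m3[, 4] * 3L
  sf3 <- size_factors(m3)
  # tripling one column triples its factor relative to every other cell
  expect_equal(unname((sf3[4] / sf[4]) / (sf3[1] / sf[1])), 3,
               tolerance = 1e-9)
})

test_that("size factors match the reference implementation up to rescaling", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(count_sim_spec(n_genes = 500, dropout_prob = 0.05,
                                        seed = 13))
  m <- drop_all_zero_genes(sim$counts)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours / exp(mean(log(ours)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-10)
})

test_that("normalization needs a usable reference and rescales columns", {
  m <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(size_factors(m), "positive_counts")
  expect_message(size_factors(m, positive_counts = TRUE), "pseudo-reference")

  sim <- simulate_counts(count_sim_spec(n_genes = 100, dropout_prob = 0,
                                        seed = 3))
  sf <- size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  expect_equal(norm[, 2], sim$counts[, 2] / sf[2])
  expect_equal(normalize_counts(sim$counts, setNames(rep(1, 23), colnames(sim$counts))),
               sim$counts, ignore_attr = TRUE)
})

test_that("detected-gene counts are exact and non-increasing in threshold", {
  m <- matrix(0, 10, 2, dimnames = list(paste0("g", 1:10), c("a", "b")))
  m[1:7, 1] <- 6     # exactly 7 genes at or above 5 in cell a
  m[8:9, 1] <- 2
  tab <- detected_genes(m, thresholds = c(1, 2, 5))
  expect_equal(tab$n_genes[tab$cell_id == "a" & tab$threshold == 5], 7)
  expect_equal(tab$n_genes[tab$cell_id == "a" & tab$threshold == 2], 9)
  expect_true(all(tab$n_genes[tab$cell_id == "b"] == 0))

  sim <- simulate_counts(count_sim_spec(n_genes = 400, seed = 21))
  norm <- normalize_counts(sim$counts, size_factors(sim$counts, positive_counts = TRUE))
  tab2 <- detected_genes(norm)
  for (cell in colnames(norm)) {
    counts_by_th <- tab2$n_genes[tab2$cell_id == cell][order(tab2$threshold[tab2$cell_id == cell])]
    expect_true(all(diff(counts_by_th) <= 0))
  }
})

test_that("the variance-stabilizing surrogate is log2(x + 1)", {
  expect_equal(vst(matrix(c(0, 1, 1023), 1)), matrix(c(0, 1, 10), 1))
  expect_error(vst(matrix(-1)), "non-negative")
})

test_that("PCA concentrates variance for low-rank data and flags degeneracy", {
  set.seed(4)
  direction <- rnorm(100)
  cells <- sapply(seq(-2, 2, length.out = 12), function(s) s * direction)
  cells <- cells + rnorm(length(cells), sd = 1e-3)
  dimnames(cells) <- list(paste0("g", 1:100), paste0("c", 1:12))
  p <- pca_top_variance(cells, n_top = 50)
  expect_gt(p$variance$proportion[1], 0.99)
  expect_true(all(diff(p$variance$proportion) <= 1e-12))
  expect_true(all(p$variance$proportion >= 0))
  expect_lte(sum(p$variance$proportion), 1 + 1e-9)

  same <- matrix(5, 20, 3, dimnames = list(paste0("g", 1:20), paste0("c", 1:3)))
  expect_true(pca_top_variance(same)$degenerate)
})

test_that("distances are metric and clustering separates shifted groups", {
  sim <- simulate_counts(count_sim_spec(n_genes = 300, de_fraction = 0.3,
                                        seed = 17))
  x <- vst(normalize_counts(sim$counts, size_factors(sim$counts, positive_counts = TRUE)))
  dc <- distance_cluster(x)
  d <- dc$distances
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:20) {
    ijk <- sample(ncol(x), 3)
    expect_lte(d[ijk[1], ijk[2]],
               d[ijk[1], ijk[3]] + d[ijk[3], ijk[2]] + 1e-9)
  }
  # the top split of the tree separates the two simulated populations
  top2 <- cutree(dc$tree, k = 2)
  expect_equal(length(unique(top2[sim$cell_groups == "Tas1r3"])), 1)
  expect_equal(length(unique(top2[sim$cell_groups == "TypeIII"])), 1)

  dup <- cbind(x[, 1], x[, 1])
  colnames(dup) <- c("a", "b")
  expect_equal(distance_cluster(dup)$distances["a", "b"], 0)
})

test_that("gene-body coverage bins and rescales as specified", {
  cov3p <- gene_body_coverage(rep(1, 50))
  expect_equal(cov3p$coverage_pct[100], 100)
  expect_true(all(cov3p$coverage_pct[1:99] == 0))

  set.seed(2)
  unif <- gene_body_coverage(runif(2e5))
  expect_equal(max(unif$coverage_pct), 100)
  expect_gt(min(unif$coverage_pct), 85)  # flat within sampling noise

  expect_error(gene_body_coverage(numeric()), "no reads")
  expect_error(gene_body_coverage(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("coverage can be restricted to the most expressed genes", {
  reads <- tibble::tibble(
    gene_id = rep(c("hi", "lo"), c(100, 100)),
    fraction = c(runif(100), rep(0.05, 100))
  )
  expr <- c(hi = 1000, lo = 1)
  cov <- gene_body_coverage(reads, gene_expression = expr, n_top_genes = 1)
  # only the "hi" gene's reads remain: first bin not dominant
  expect_lt(cov$coverage_pct[1], 100 / 3)
})
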