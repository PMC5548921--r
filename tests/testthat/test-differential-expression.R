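two_group_matrix <- function(n_genes, mu_a, mu_b, alpha, n_a = 9, n_b = 14,
                             seed = 1) {
  withr::with_seed(seed, {
    draw <- function(mu, n) {
      matrix(if (alpha == 0) rpois(n_genes * n, mu)
             else rnbinom(n_genes * n, size = 1 / alpha, mu = mu),
             n_genes, n)
    }
    m <- cbind(draw(mu_a, n_a), draw(mu_b, n_b))
    dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("c%02d", seq_len(n_a + n_b)))
    list(m = m, groups = rep(c("Tas1r3", "TypeIII"), c(n_a, n_b)))
  })
}

test_that("dispersion estimation recovers known alpha regimes", {
  # Poisson data: final alpha collapses to ~0 at decent means
  pois <- two_group_matrix(1000, 80, 80, alpha = 0, n_a = 25, n_b = 25,
                           seed = 2)
  d0 <- estimate_dispersions(pois$m, pois$groups)
  expect_lte(median(d0$final_alpha[d0$base_mean >= 50]), 0.05)

  # NB alpha = 0.5 with many cells: raw MoM is consistent
  nb <- two_group_matrix(500, 100, 100, alpha = 0.5, n_a = 100, n_b = 100,
                         seed = 3)
  d5 <- estimate_dispersions(nb$m, nb$groups)
  expect_gte(median(d5$raw_alpha), 0.4)
  expect_lte(median(d5$raw_alpha), 0.6)

  # constant counts within groups: zero raw dispersion
  const <- matrix(rep(c(5, 9), each = 6), 2, 6, byrow = TRUE,
                  dimnames = list(c("g1", "g2"), paste0("c", 1:6)))
  dc <- estimate_dispersions(const, rep(c("a", "b"), each = 3))
  expect_equal(dc$raw_alpha, c(0, 0))

  expect_error(estimate_dispersions(const, c("a", "a", "a", "a", "a", "b")),
               "at least 2 cells")
})

test_that("identical groups give zero fold change and p near 1", {
  m <- matrix(rep(c(10, 50, 200), 6), 3, 6,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:6)))
  res <- wald_test(m, rep(c("a", "b"), each = 3))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
})

test_that("swapping group labels negates log2fc and keeps p", {
  sim <- two_group_matrix(200, 50, 120, alpha = 0.3, seed = 5)
  disp <- estimate_dispersions(sim$m, sim$groups)
  fwd <- wald_test(sim$m, factor(sim$groups, c("Tas1r3", "TypeIII")), disp)
  rev <- wald_test(sim$m, factor(sim$groups, c("TypeIII", "Tas1r3")), disp)
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("the Wald test recovers a 4-fold effect at moderate depth", {
  # mu 100 vs 400, alpha = 0.1, 15 vs 15 cells, 200 replicate genes
  sim <- two_group_matrix(200, 100, 400, alpha = 0.1, n_a = 15, n_b = 15,
                          seed = 8)
  res <- wald_test(sim$m, sim$groups)
  expect_gte(median(res$log2fc), 1.8)
  expect_lte(median(res$log2fc), 2.2)
})

test_that("null p-values are close to uniform", {
  sim <- two_group_matrix(5000, 60, 60, alpha = 0.5, seed = 10)
  res <- wald_test(sim$m, sim$groups)
  ks <- suppressWarnings(ks.test(res$p_value, "punif")$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("BH adjustment reproduces the hand step-up and the filter contract", {
  res <- tibble::tibble(gene_id = paste0("g", 1:4),
                        base_mean = c(100, 100, 100, 100),
                        log2fc = 1, p_value = c(0.01, 0.02, 0.03, 0.04))
  adj <- bh_adjust(res, independent_filter = FALSE)
  expect_equal(adj$fdr, rep(0.04, 4))

  res$p_value <- rep(1, 4)
  expect_equal(bh_adjust(res, independent_filter = FALSE)$fdr, rep(1, 4))

  # low-mean genes are excluded from m and get NA fdr
  res2 <- tibble::tibble(
    gene_id = paste0("g", 1:100),
    base_mean = c(rep(0.01, 50), rep(100, 50)),
    log2fc = 0,
    p_value = c(runif(50, 0.5, 1), rep(c(1e-6, 0.5), 25))
  )
  adj2 <- bh_adjust(res2, fdr_max = 0.05)
  th <- attr(adj2, "filter_threshold")
  expect_true(all(is.na(adj2$fdr[adj2$base_mean < th])))
  kept <- !is.na(adj2$fdr)
  expect_equal(adj2$fdr[kept],
               p.adjust(adj2$p_value[kept], method = "BH"))
})

test_that("the DE filters partition passing genes by sign", {
  res <- tibble::tibble(
    gene_id = paste0("g", 1:9),
    base_mean = c(rep(100, 7), 5, 100),
    log2fc = c(2, 3, 4, -2, -3, -4, -5, 6, 0.5),
    fdr = c(rep(0.01, 8), 0.01)
  )
  out <- apply_de_filters(res)
  expect_equal(length(out$up_b), 3)  # g1..g3: positive, pass
  expect_equal(length(out$up_a), 4)  # g4..g7: negative, pass
  expect_equal(out$n_passing, 7)     # g8 fails mean, g9 fails fc

  res$fdr[1] <- NA  # filtered genes can never pass
  expect_equal(length(apply_de_filters(res)$up_b), 2)

  empty <- res[0, ]
  out0 <- apply_de_filters(empty)
  expect_equal(out0$n_passing, 0)
  expect_equal(out0$up_a, character(0))
})

test_that("planted 4-fold effects at adequate depth mostly pass the filters", {
  sim <- simulate_counts(count_sim_spec(
    n_genes = 2000, de_fraction = 0.1, log2fc_range = c(2, 2),
    mean_log_mu = log(300), sd_log_mu = 0.5, dispersion = 0.5,
    dropout_prob = 0, depth_sd_log = 0.3, seed = 29))
  fit <- run_de(sim$counts, sim$cell_groups)
  td <- tidy(fit)
  de_ids <- sim$truth$genes$gene_id[sim$truth$genes$is_de]
  power <- mean(td$passes_filters[td$gene_id %in% de_ids])
  expect_gte(power, 0.8)
})

test_that("a normal reference would inflate the far tail the t reference controls", {
  # at the study sizes the log ratio of NB group means is skewed: even with
  # the true dispersion plugged in, normal two-sided p-values overshoot
  # their nominal far-tail rate by well over 50%
  withr::with_seed(61, {
    n <- 2e5
    alpha <- 0.5
    mu <- rlnorm(n, log(50), 1)
    ma <- rowMeans(matrix(rnbinom(n * 9, size = 1 / alpha,
                                  mu = rep(mu, each = 9)), n, byrow = TRUE))
    mb <- rowMeans(matrix(rnbinom(n * 14, size = 1 / alpha,
                                  mu = rep(mu, each = 14)), n, byrow = TRUE))
    lfc <- log2((mb + 0.5) / (ma + 0.5))
    ln2sq <- log(2)^2
    va <- (ma + alpha * ma^2) / (9 * (ma + 0.5)^2 * ln2sq)
    vb <- (mb + alpha * mb^2) / (14 * (mb + 0.5)^2 * ln2sq)
    z <- lfc / sqrt(va + vb)
    p_norm <- 2 * pnorm(-abs(z))
    p_t <- 2 * pt(-abs(z), df = 21)
    expect_gt(mean(p_norm < 1e-4) / 1e-4, 1.5)   # normal: inflated
    expect_lt(mean(p_t < 1e-4) / 1e-4, 1.5)      # t: controlled
  })
})

test_that("raising fdr_max never shrinks the passing set", {
  sim <- simulate_counts(count_sim_spec(n_genes = 800, de_fraction = 0.15,
                                        seed = 19))
  fit <- run_de(sim$counts, sim$cell_groups)
  strict <- apply_de_filters(fit$results, de_config(fdr_max = 0.01))
  loose <- apply_de_filters(fit$results, de_config(fdr_max = 0.1))
  expect_true(all(strict$passing$gene_id %in% loose$passing$gene_id))
})

test_that("run_de recovers the planted marker structure end to end", {
  sim <- simulate_counts(count_sim_spec(n_genes = 600, de_fraction = 0,
                                        markers = "table1", seed = 23))
  fit <- run_de(sim$counts, sim$cell_groups)
  td <- tidy(fit)
  mk <- table1_markers()
  got <- td[match(mk$gene_symbol, td$gene_id), ]
  # every marker is recovered with the right orientation
  expect_true(all(sign(got$log2fc) == sign(mk$log2fc)))
  expect_true(all(got$passes_filters))
  g <- glance(fit)
  expect_gte(g$n_up_numerator, sum(mk$log2fc > 0))
  expect_gte(g$n_up_denominator, sum(mk$log2fc < 0))
})
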