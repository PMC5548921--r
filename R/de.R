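#' Differential-expression filter configuration
#'
#' The gene-list filters applied after testing: minimum average normalized
#' count (10 for the main functional list, 50 for the smaller focus list),
#' minimum absolute fold change of 2, and FDR at most 0.05.
#'
#' @param min_avg_count Minimum base mean in normalized counts (default 10).
#' @param abs_fc_min Minimum absolute fold change, linear scale (default 2).
#' @param fdr_max Maximum FDR (default 0.05).
#' @return A list of class `de_config`.
#' @export
de_config <- function(min_avg_count = 10, abs_fc_min = 2, fdr_max = 0.05) {
  if (min_avg_count <= 0 || abs_fc_min <= 0) {
    abort("thresholds must be positive.")
  }
  if (fdr_max <= 0 || fdr_max >= 1) abort("`fdr_max` must lie in (0, 1).")
  structure(list(min_avg_count = min_avg_count, abs_fc_min = abs_fc_min,
                 fdr_max = fdr_max), class = "de_config")
}

#' Negative-binomial Wald test for two groups
#'
#' Per gene: `log2fc = log2((mean_b + c) / (mean_a + c))` with pseudo-count
#' `c` (default 0.5 normalized counts, handling near-zero group means); the
#' standard error comes from the NB delta method,
#' `Var(log2 mean_g) = (m_g + alpha m_g^2) / (n_g (m_g + c)^2 ln(2)^2)`,
#' summed over the two groups with the gene's final dispersion; the Wald
#' statistic `z = log2fc / se` is referred, two-sided, to a t distribution
#' with the within-group degrees of freedom (`n - 2`). The t reference is a
#' small-sample correction: with 9 + 14 cells the log ratio of NB group
#' means has visibly heavier tails than normal, and a normal reference
#' inflates the extreme-tail rate enough to break FDR control (see the
#' methods vignette).
#'
#' Orientation: group A is the denominator. With the study's labels the
#' denominator is the `Tas1r3` population, so positive fold changes read
#' "up-regulated in type III cells".
#'
#' @param normalized Normalized count matrix, genes x cells.
#' @param groups Two-level factor/character over cells; the *first* level is
#'   the denominator group A.
#' @param dispersions Tibble from [estimate_dispersions()] (computed here
#'   when `NULL`).
#' @param pseudo_count Fold-change pseudo-count `c` (default 0.5).
#' @return Tibble `gene_id`, `base_mean`, `mean_a`, `mean_b`, `log2fc`,
#'   `se_log2fc`, `wald_z`, `p_value`.
#' @export
wald_test <- function(normalized, groups, dispersions = NULL,
                      pseudo_count = 0.5) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) abort("exactly two groups are required.")
  if (any(table(groups) == 0)) abort("both groups need at least one cell.")
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(normalized, groups)
  }
  ia <- groups == levels(groups)[1]
  ib <- groups == levels(groups)[2]
  na <- sum(ia); nb <- sum(ib)
  mean_a <- unname(rowMeans(normalized[, ia, drop = FALSE]))
  mean_b <- unname(rowMeans(normalized[, ib, drop = FALSE]))
  alpha <- dispersions$final_alpha[match(rownames(normalized),
                                         dispersions$gene_id)]
  lfc <- log2((mean_b + pseudo_count) / (mean_a + pseudo_count))
  ln2sq <- log(2)^2
  v_a <- (mean_a + alpha * mean_a^2) / (na * (mean_a + pseudo_count)^2 * ln2sq)
  v_b <- (mean_b + alpha * mean_b^2) / (nb * (mean_b + pseudo_count)^2 * ln2sq)
  se <- sqrt(v_a + v_b)
  z <- ifelse(se > 0, lfc / se, 0)
  df_within <- na + nb - 2
  p <- ifelse(se > 0, 2 * stats::pt(-abs(z), df = df_within), 1)
  tibble(gene_id = rownames(normalized),
         base_mean = unname(rowMeans(normalized)),
         mean_a = mean_a, mean_b = mean_b,
         log2fc = lfc, se_log2fc = se, wald_z = z, p_value = p)
}

#' Benjamini-Hochberg adjustment with independent filtering
#'
#' Genes whose base mean falls below a data-chosen filter threshold are
#' removed from the multiple-testing universe before the step-up BH
#' adjustment and receive an undefined (`NA`) FDR; they are never counted in
#' the BH `m`. The threshold is chosen over a quantile grid of the base mean
#' (default the 0 to 95th percentiles in 20 equal steps) to maximize the
#' number of discoveries at `fdr_max`, mirroring the practice of excluding
#' genes with counts too low to ever reach significance. Ties in the number
#' of discoveries resolve to the lowest threshold.
#'
#' @param results Tibble from [wald_test()] with `base_mean` and `p_value`.
#' @param independent_filter Apply the filter (default `TRUE`; `FALSE`
#'   adjusts all genes).
#' @param fdr_max FDR level the filter optimizes discoveries at (default
#'   0.05).
#' @param grid_max_quantile,grid_steps Grid definition (defaults 0.95, 20).
#' @return `results` with an `fdr` column (`NA` for filtered genes); the
#'   chosen base-mean cutoff is attached as attribute `filter_threshold`.
#' @export
bh_adjust <- function(results, independent_filter = TRUE, fdr_max = 0.05,
                      grid_max_quantile = 0.95, grid_steps = 20) {
  if (!all(c("base_mean", "p_value") %in% names(results))) {
    abort("`results` needs `base_mean` and `p_value` columns.")
  }
  if (nrow(results) == 0) {
    results$fdr <- numeric(0)
    attr(results, "filter_threshold") <- 0
    return(results)
  }
  if (!independent_filter) {
    results$fdr <- p.adjust(results$p_value, method = "BH")
    attr(results, "filter_threshold") <- 0
    return(results)
  }
  grid <- quantile(results$base_mean,
                   probs = seq(0, grid_max_quantile, length.out = grid_steps),
                   names = FALSE)
  grid <- unique(grid)
  n_disc <- map_dbl(grid, function(th) {
    keep <- results$base_mean >= th
    if (!any(keep)) return(0)
    sum(p.adjust(results$p_value[keep], method = "BH") <= fdr_max)
  })
  th <- grid[which.max(n_disc)]  # which.max takes the first (lowest) tie
  keep <- results$base_mean >= th
  fdr <- rep(NA_real_, nrow(results))
  fdr[keep] <- p.adjust(results$p_value[keep], method = "BH")
  results$fdr <- fdr
  attr(results, "filter_threshold") <- th
  results
}

#' Apply the differential-expression gene-list filters
#'
#' Partitions genes passing `|fold change| >= abs_fc_min`,
#' `base_mean >= min_avg_count` and `fdr <= fdr_max` by the sign of the fold
#' change. Genes with undefined FDR (independent filtering) never pass.
#'
#' @param results Tibble from [bh_adjust()] with `log2fc`, `base_mean`,
#'   `fdr`.
#' @param cfg A [de_config()].
#' @return A list with `up_b` (log2fc > 0: up in the numerator group, type
#'   III), `up_a` (log2fc < 0: up in the denominator group, Tas1r3),
#'   `passing` (tibble of passing rows with a `direction` column), and
#'   `n_passing`.
#' @export
apply_de_filters <- function(results, cfg = de_config()) {
  needed <- c("gene_id", "log2fc", "base_mean", "fdr")
  if (!all(needed %in% names(results))) {
    abort(paste0("`results` needs columns ",
                 paste(needed, collapse = ", "), "."))
  }
  pass <- !is.na(results$fdr) &
    results$fdr <= cfg$fdr_max &
    abs(results$log2fc) >= log2(cfg$abs_fc_min) &
    results$base_mean >= cfg$min_avg_count
  passing <- results[pass, , drop = FALSE]
  passing$direction <- ifelse(passing$log2fc > 0, "up_b", "up_a")
  list(up_b = passing$gene_id[passing$log2fc > 0],
       up_a = passing$gene_id[passing$log2fc < 0],
       passing = as_tibble(passing),
       n_passing = nrow(passing))
}

#' Run the full two-group differential expression analysis
#'
#' Convenience wrapper: drops all-zero genes, computes size factors and
#' normalized counts, estimates dispersions, runs the Wald test, adjusts
#' with independent filtering, and applies the gene-list filters.
#'
#' @param counts Raw integer count matrix, genes x cells.
#' @param groups Two-level factor/character over cells; first level =
#'   denominator (`Tas1r3` by convention).
#' @param cfg A [de_config()].
#' @param independent_filter Passed to [bh_adjust()].
#' @param pseudo_count Passed to [wald_test()].
#' @return An object of class `taste_de` with elements `results` (full
#'   per-gene tibble), `lists` (from [apply_de_filters()]), `size_factors`,
#'   `dispersions`, `groups`, `cfg`, `filter_threshold`.
#' @export
run_de <- function(counts, groups, cfg = de_config(),
                   independent_filter = TRUE, pseudo_count = 0.5) {
  counts <- drop_all_zero_genes(counts)
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  groups <- factor(groups, levels = unique(groups))
  disp <- estimate_dispersions(norm, groups)
  res <- wald_test(norm, groups, disp, pseudo_count = pseudo_count)
  res <- bh_adjust(res, independent_filter = independent_filter,
                   fdr_max = cfg$fdr_max)
  lists <- apply_de_filters(res, cfg)
  structure(
    list(results = res, lists = lists, size_factors = sf,
         dispersions = disp, groups = groups, cfg = cfg,
         filter_threshold = attr(res, "filter_threshold")),
    class = "taste_de"
  )
}

#' @export
print.taste_de <- function(x, ...) {
  lv <- levels(x$groups)
  cat("Two-group NB differential expression (", lv[2], " / ", lv[1], ")\n",
      sep = "")
  cat("  genes tested: ", nrow(x$results),
      " (independent-filter base-mean cutoff ",
      signif(x$filter_threshold, 3), ")\n", sep = "")
  cat("  passing filters: ", x$lists$n_passing,
      " (", length(x$lists$up_b), " up in ", lv[2], ", ",
      length(x$lists$up_a), " up in ", lv[1], ")\n", sep = "")
  invisible(x)
}

#' Tidy a differential expression fit
#'
#' @param x A `taste_de` object.
#' @param ... Unused.
#' @return The per-gene results tibble with a `passes_filters` column.
#' @method tidy taste_de
#' @export
tidy.taste_de <- function(x, ...) {
  out <- x$results
  out$passes_filters <- out$gene_id %in% x$lists$passing$gene_id
  as_tibble(out)
}

#' One-row summary of a differential expression fit
#'
#' @inheritParams tidy.taste_de
#' @method glance taste_de
#' @export
glance.taste_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x$results),
    n_tested = sum(!is.na(x$results$fdr)),
    filter_threshold = x$filter_threshold,
    n_passing = x$lists$n_passing,
    n_up_numerator = length(x$lists$up_b),
    n_up_denominator = length(x$lists$up_a)
  )
}
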