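#' Moment-based negative-binomial dispersion estimates with trend shrinkage
#'
#' For each gene, a raw dispersion is estimated from within-group moments of
#' the normalized counts under `Var = mu + alpha * mu^2`:
#' `alpha_hat = max(0, sum_g df_g (s2_g - m_g) / sum_g df_g m_g^2)` pooled
#' over the two groups (`df_g = n_g - 1`). A mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` is fitted by least squares across genes, and
#' the final per-gene value shrinks the raw estimate toward the trend by
#' precision weighting: the weight on the raw value is the estimated
#' between-gene variance of true dispersions around the trend (`tau2`, a
#' method-of-moments estimate floored at zero), and the weight on the trend
#' is the sampling variance of the raw estimator
#' (`(alpha + 1/mu)^2 (2/df + 6 alpha/n)`, the gamma-limit approximation).
#' With few cells the raw estimator is noisy (relative error near 50% at
#' 9 + 14 cells), so when gene-to-gene dispersion differences are small the
#' final estimates collapse onto the trend; when they are large the raw
#' values dominate.
#'
#' @param normalized Normalized count matrix, genes x cells.
#' @param groups Factor or character vector of length `ncol(normalized)`
#'   with exactly two levels; each group needs at least 2 cells.
#' @return Tibble `gene_id`, `base_mean`, `raw_alpha`, `fitted_alpha`,
#'   `final_alpha`, with attributes `trend` (`a0`, `a1`) and `tau2`.
#' @export
estimate_dispersions <- function(normalized, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) abort("exactly two groups are required.")
  if (any(table(groups) < 2)) {
    abort("each group needs at least 2 cells to estimate dispersion.")
  }
  ga <- which(groups == levels(groups)[1])
  gb <- which(groups == levels(groups)[2])
  stats_for <- function(idx) {
    m <- unname(rowMeans(normalized[, idx, drop = FALSE]))
    s2 <- unname(apply(normalized[, idx, drop = FALSE], 1, var))
    list(m = m, s2 = s2, df = length(idx) - 1)
  }
  a <- stats_for(ga)
  b <- stats_for(gb)
  num <- a$df * (a$s2 - a$m) + b$df * (b$s2 - b$m)
  den <- a$df * a$m^2 + b$df * b$m^2
  raw <- ifelse(den > 0, pmax(0, num / den), 0)

  base_mean <- unname(rowMeans(normalized))
  ok <- base_mean > 0 & is.finite(raw)
  fit <- lm(raw[ok] ~ I(1 / base_mean[ok]))
  a0 <- max(coef(fit)[1], 0)
  a1 <- max(coef(fit)[2], 0)
  fitted_alpha <- ifelse(base_mean > 0, a0 + a1 / base_mean, a0)

  df_within <- a$df + b$df
  n_cells <- length(ga) + length(gb)
  # sampling variance of the raw MoM estimator (gamma-limit approximation),
  # evaluated at the trend to avoid feeding back the raw noise
  var_raw <- (fitted_alpha + 1 / pmax(base_mean, 1e-8))^2 *
    (2 / df_within + 6 * fitted_alpha / n_cells)
  resid2 <- (raw - fitted_alpha)^2
  tau2 <- max(mean(resid2[ok]) - mean(var_raw[ok]), 0)
  w_raw <- tau2 / (tau2 + var_raw)
  final <- w_raw * raw + (1 - w_raw) * fitted_alpha

  out <- tibble(gene_id = rownames(normalized), base_mean = base_mean,
                raw_alpha = raw, fitted_alpha = fitted_alpha,
                final_alpha = pmax(final, 0))
  attr(out, "trend") <- c(a0 = unname(a0), a1 = unname(a1))
  attr(out, "tau2") <- tau2
  out
}
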