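#' Median-of-ratios size factors
#'
#' The library-size normalization used throughout the pipeline: a reference
#' pseudo-sample is formed as the per-gene geometric mean across cells
#' (restricted to genes with nonzero counts in *every* cell), and each
#' cell's size factor is the median over those genes of its count divided by
#' the reference. Factors are rescaled to geometric mean 1, so normalized
#' counts stay on the scale of the raw counts.
#'
#' Sparse single-cell matrices can lack genes counted in every cell; the
#' opt-in `positive_counts` reference takes each gene's geometric mean over
#' its nonzero entries instead and uses every gene with at least one nonzero
#' count, at the cost of a reference no longer grounded in fully observed
#' genes (a message notes when it is active).
#'
#' @param counts Integer matrix, genes x cells (raw counts).
#' @param positive_counts Use the nonzero-entry geometric-mean reference
#'   (default `FALSE`).
#' @return Named numeric vector of positive per-cell factors.
#' @export
size_factors <- function(counts, positive_counts = FALSE) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2) abort("need at least 2 cells to normalize.")
  if (positive_counts) {
    message("size_factors: using positive-counts pseudo-reference.")
    logref <- apply(counts, 1, function(x) {
      nz <- x > 0
      if (!any(nz)) -Inf else mean(log(x[nz]))
    })
    usable <- is.finite(logref)
  } else {
    logref <- rowMeans(log(counts))  # -Inf when any zero in the row
    usable <- is.finite(logref)
    if (!any(usable)) {
      abort(paste0(
        "no gene has nonzero counts in every cell, so the median-of-ratios ",
        "reference is undefined; consider `positive_counts = TRUE`."))
    }
  }
  sf <- apply(counts[usable, , drop = FALSE], 2, function(x) {
    ratios <- log(x) - logref[usable]
    exp(median(ratios[is.finite(ratios)]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    abort("size factors are undefined (non-positive median ratio).")
  }
  sf <- sf / exp(mean(log(sf)))  # fix the scale: geometric mean 1
  sf
}

#' Normalize counts by size factors
#'
#' @param counts Matrix, genes x cells.
#' @param factors Named per-cell factors from [size_factors()].
#' @return Real-valued matrix `counts[g, c] / factors[c]`.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  if (length(factors) != ncol(counts)) {
    abort("one size factor per cell is required.")
  }
  sweep(counts, 2, factors, "/")
}

#' Detected genes per cell across expression thresholds
#'
#' For each cell, the number of genes whose normalized count meets or
#' exceeds each threshold. Used to separate genes with negligible expression
#' from meaningfully expressed genes; the count is non-increasing in the
#' threshold by construction.
#'
#' @param normalized Normalized matrix from [normalize_counts()].
#' @param thresholds Normalized-count thresholds (default 1--50).
#' @return Tibble `cell_id`, `threshold`, `n_genes`.
#' @export
detected_genes <- function(normalized, thresholds = c(1, 2, 5, 10, 20, 50)) {
  if (any(thresholds <= 0)) abort("thresholds must be positive.")
  rows <- map(sort(thresholds), function(th) {
    tibble(cell_id = colnames(normalized), threshold = th,
           n_genes = unname(colSums(normalized >= th)))
  })
  list_rbind(rows)
}

#' Variance-stabilizing transform (log2 pseudo-count surrogate)
#'
#' `log2(x + 1)`, applied elementwise. A deliberate simplification of a
#' fitted dispersion-based transform: it is monotone, maps 0 to 0, and is
#' used only for pattern-level analyses (PCA, distances, heat maps), where
#' the qualitative structure is insensitive to the exact transform.
#'
#' @param normalized Normalized count matrix.
#' @return Transformed matrix.
#' @export
vst <- function(normalized) {
  if (any(normalized < 0)) abort("normalized counts must be non-negative.")
  log2(normalized + 1)
}
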