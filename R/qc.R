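#' PCA of cells over the most variable genes
#'
#' Genes are ranked by row variance of the transformed matrix, the top
#' `n_top` are retained, and cells are projected by centered (unscaled)
#' principal component analysis. Variance proportions are each component's
#' share of the total variance of the centered data.
#'
#' @param transformed Matrix from [vst()], genes x cells.
#' @param n_top Number of top-variance genes (default 500, capped at the
#'   number of genes).
#' @return A list with `scores` (tibble `cell_id`, `PC1`, `PC2`, ...),
#'   `variance` (tibble `component`, `proportion`), `genes_used`, and
#'   `degenerate` (`TRUE` when the data carry no variance, e.g. identical
#'   cells).
#' @export
pca_top_variance <- function(transformed, n_top = 500) {
  if (ncol(transformed) < 2) abort("PCA needs at least 2 cells.")
  if (n_top > nrow(transformed)) n_top <- nrow(transformed)
  rv <- apply(transformed, 1, var)
  top <- order(rv, decreasing = TRUE)[seq_len(n_top)]
  x <- t(transformed[top, , drop = FALSE])
  total_var <- sum(apply(x, 2, var))
  if (total_var == 0) {
    return(list(
      scores = tibble(cell_id = colnames(transformed)),
      variance = tibble(component = integer(), proportion = numeric()),
      genes_used = rownames(transformed)[top], degenerate = TRUE))
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  prop <- p$sdev^2 / sum(p$sdev^2)
  scores <- as_tibble(p$x)
  scores <- bind_cols(tibble(cell_id = rownames(x)), scores)
  list(scores = scores,
       variance = tibble(component = seq_along(prop), proportion = prop),
       genes_used = rownames(transformed)[top],
       degenerate = FALSE)
}

#' Euclidean distances and hierarchical clustering of cells
#'
#' Pairwise Euclidean distances between cells over all genes of the
#' transformed matrix, followed by agglomerative clustering (complete
#' linkage by default; the linkage is configurable).
#'
#' @param transformed Matrix from [vst()], genes x cells.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A list with `distances` (symmetric matrix, zero diagonal),
#'   `tree` (an `hclust`), and `linkage`.
#' @export
distance_cluster <- function(transformed, linkage = "complete") {
  if (ncol(transformed) < 2) abort("clustering needs at least 2 cells.")
  d <- dist(t(transformed), method = "euclidean")
  list(distances = as.matrix(d), tree = hclust(d, method = linkage),
       linkage = linkage)
}

#' Export a dendrogram in Newick format
#'
#' @param tree An `hclust`, e.g. from [distance_cluster()].
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export needs the `ape` package.")
  }
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Gene-body coverage profile in 100 quantile bins
#'
#' Summarizes per-read relative positions along the 5' to 3' gene body
#' (fractions in `[0, 1]`) as a 100-bin histogram rescaled so the maximum
#' bin equals 100, the quality-control profile used to reveal the 3' bias
#' of oligo(dT)-primed amplification. Bins are half-open
#' `[i/100, (i+1)/100)`; the last bin is closed. When a `gene_id` column
#' and per-gene expression are supplied, reads are restricted to the
#' `n_top_genes` most expressed genes before binning.
#'
#' @param reads Numeric vector of fractions, or a data frame with columns
#'   `fraction` and optionally `gene_id`.
#' @param gene_expression Optional named vector of per-gene expression used
#'   to restrict to the most expressed genes (requires `gene_id`).
#' @param n_top_genes Number of genes retained when restricting (default
#'   1000).
#' @return Tibble `bin` (1--100), `percentile` (bin upper edge, percent),
#'   `coverage_pct` (percent of the maximum bin).
#' @export
gene_body_coverage <- function(reads, gene_expression = NULL,
                               n_top_genes = 1000) {
  if (is.data.frame(reads)) {
    if (!"fraction" %in% names(reads)) {
      abort("`reads` data frame needs a `fraction` column.")
    }
    if (!is.null(gene_expression)) {
      if (!"gene_id" %in% names(reads)) {
        abort("restricting by expression needs a `gene_id` column.")
      }
      top <- names(sort(gene_expression, decreasing = TRUE))
      top <- head(top, n_top_genes)
      reads <- reads[reads$gene_id %in% top, ]
    }
    fractions <- reads$fraction
  } else {
    fractions <- reads
  }
  if (length(fractions) == 0) abort("no reads to profile.")
  if (any(fractions < 0 | fractions > 1)) {
    abort("read fractions must lie in [0, 1].")
  }
  bin <- pmin(floor(fractions * 100), 99) + 1
  counts <- tabulate(bin, nbins = 100)
  tibble(bin = 1:100, percentile = 1:100,
         coverage_pct = 100 * counts / max(counts))
}
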