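#' Marker genes packaged with the count simulator
#'
#' Returns the packaged table of taste-cell marker genes: type II markers
#' (sweet/umami receptor subunits and their transduction cascade, e.g.
#' `Plcb2`, `Trpm5`) and type III markers (e.g. `Pkd2l1`, `Snap25`, `Gad1`),
#' with their average normalized counts in each population, the reported
#' log2 fold change (type III over Tas1r3-positive orientation; type II
#' markers are therefore negative), and the reported FDR.
#'
#' The average-count and log2FC columns are not mutually consistent as plain
#' mean ratios (the fold changes come from a negative-binomial GLM fit on
#' zero-heavy single-cell data, where the coefficient can exceed the ratio of
#' plain means). The `"table1"` preset of [simulate_counts()] therefore takes
#' the *dominant* population's mean and the log2FC as simulation truth and
#' derives the minor population's mean from them.
#'
#' @return Tibble with columns `gene_symbol`, `marked_cell_type`,
#'   `avg_count_tas1r3`, `avg_count_type3`, `log2fc`, `fdr`.
#' @export
table1_markers <- function() {
  path <- system.file("extdata", "table1_markers.tsv",
                      package = "tastecellseq", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Specify a simulated two-population count matrix
#'
#' Counts are drawn from a negative-binomial model,
#' `NB(mean = depth_c * mu_{g,group(c)}, Var = mu + alpha * mu^2)`, then
#' zeroed with probability `dropout_prob` (Bernoulli zero inflation,
#' independent of the mean) to emulate the drop-out events characteristic of
#' single-cell amplification. Group B means equal group A means times
#' `2^log2fc` for differentially expressed genes.
#'
#' @param n_genes Number of genes.
#' @param n_cells_a,n_cells_b Cells in group A (`Tas1r3`, the fold-change
#'   denominator) and group B (`TypeIII`, the numerator). Defaults are the
#'   study's group sizes, 9 and 14.
#' @param mean_log_mu,sd_log_mu Location/scale (natural log) of the lognormal
#'   baseline gene means.
#' @param de_fraction Proportion of genes differentially expressed, in
#'   `[0, 1]`.
#' @param log2fc_range Magnitude range from which true |log2FC| values are
#'   drawn uniformly, with random sign; the default 5--15 matches the
#'   marker-gene effect sizes the pipeline is meant to recover.
#' @param dispersion NB dispersion `alpha` (`Var = mu + alpha mu^2`).
#' @param depth_sd_log Lognormal SD of per-cell depth factors (0 = equal
#'   depth).
#' @param dropout_prob Per-gene-per-cell probability of forcing a zero.
#' @param markers Either `NULL` or `"table1"` to prepend the packaged marker
#'   genes with their reported effect sizes as simulation truth.
#' @param seed Integer seed.
#' @return A list of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 2000, n_cells_a = 9, n_cells_b = 14,
                           mean_log_mu = log(50), sd_log_mu = 1,
                           de_fraction = 0.1, log2fc_range = c(5, 15),
                           dispersion = 0.5, depth_sd_log = 0.3,
                           dropout_prob = 0.1, markers = NULL, seed = 1L) {
  if (de_fraction < 0 || de_fraction > 1) {
    abort("`de_fraction` must lie in [0, 1].")
  }
  if (dropout_prob < 0 || dropout_prob > 1) {
    abort("`dropout_prob` must lie in [0, 1].")
  }
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (n_cells_a < 1 || n_cells_b < 1) abort("need at least one cell per group.")
  if (!is.null(markers)) markers <- match.arg(markers, "table1")
  structure(
    list(n_genes = n_genes, n_cells_a = n_cells_a, n_cells_b = n_cells_b,
         mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
         de_fraction = de_fraction, log2fc_range = log2fc_range,
         dispersion = dispersion, depth_sd_log = depth_sd_log,
         dropout_prob = dropout_prob, markers = markers,
         seed = as.integer(seed)),
    class = "count_sim_spec"
  )
}

rnbinom_mu <- function(n, mu, alpha) {
  # alpha = 0 degenerates to Poisson (size -> Inf)
  if (alpha == 0) rpois(n, mu) else rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate a genes-by-cells count matrix with ground truth
#'
#' @param spec A [count_sim_spec()].
#' @return A list with `counts` (integer matrix, genes x cells),
#'   `cell_groups` (named character, `"Tas1r3"`/`"TypeIII"`), and `truth`
#'   (list of `genes`: tibble `gene_id`, `mu_a`, `mu_b`, `true_log2fc`,
#'   `is_de`; and `cells`: tibble `cell_id`, `group`, `depth_factor`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  n_cells <- spec$n_cells_a + spec$n_cells_b
  groups <- c(rep("Tas1r3", spec$n_cells_a), rep("TypeIII", spec$n_cells_b))
  cell_ids <- sprintf("%s_%02d", ifelse(groups == "Tas1r3", "T3", "TIII"),
                      unlist(lapply(table(factor(groups, c("Tas1r3", "TypeIII"))), seq_len)))

  genes <- with_seed(derive_seed(spec$seed, "counts/genes"), {
    mu_a <- rlnorm(spec$n_genes, spec$mean_log_mu, spec$sd_log_mu)
    is_de <- runif(spec$n_genes) < spec$de_fraction
    lfc <- ifelse(
      is_de,
      runif(spec$n_genes, spec$log2fc_range[1], spec$log2fc_range[2]) *
        sample(c(-1, 1), spec$n_genes, replace = TRUE),
      0
    )
    tibble(gene_id = sprintf("gene_%05d", seq_len(spec$n_genes)),
           mu_a = mu_a, true_log2fc = lfc, is_de = is_de)
  })

  if (!is.null(spec$markers)) {
    mk <- table1_markers()
    dominant <- ifelse(mk$marked_cell_type == "Tas1r3",
                       mk$avg_count_tas1r3, mk$avg_count_type3)
    # dominant mean and reported log2FC define the truth; the minor mean
    # follows as dominant * 2^-|log2fc|
    mu_a <- ifelse(mk$log2fc < 0, dominant, dominant * 2^(-abs(mk$log2fc)))
    marker_rows <- tibble(gene_id = mk$gene_symbol, mu_a = mu_a,
                          true_log2fc = mk$log2fc, is_de = TRUE)
    genes <- bind_rows(marker_rows, genes)
  }

  genes$mu_b <- genes$mu_a * 2^genes$true_log2fc
  genes <- genes[, c("gene_id", "mu_a", "mu_b", "true_log2fc", "is_de")]

  depth <- with_seed(derive_seed(spec$seed, "counts/depth"), {
    if (spec$depth_sd_log == 0) rep(1, n_cells)
    else rlnorm(n_cells, 0, spec$depth_sd_log)
  })

  mu_mat <- cbind(
    matrix(genes$mu_a, nrow(genes), spec$n_cells_a),
    matrix(genes$mu_b, nrow(genes), spec$n_cells_b)
  ) * rep(depth, each = nrow(genes))

  counts <- with_seed(derive_seed(spec$seed, "counts/draws"), {
    m <- matrix(rnbinom_mu(length(mu_mat), as.vector(mu_mat), spec$dispersion),
                nrow(genes), n_cells)
    if (spec$dropout_prob > 0) {
      m[matrix(runif(length(m)) < spec$dropout_prob, nrow(m))] <- 0L
    }
    m
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes$gene_id, cell_ids)

  list(
    counts = counts,
    cell_groups = setNames(groups, cell_ids),
    truth = list(
      genes = genes,
      cells = tibble(cell_id = cell_ids, group = groups, depth_factor = depth)
    )
  )
}
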