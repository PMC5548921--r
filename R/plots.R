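#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' MA plot of a differential expression fit
#'
#' Mean expression against log2 fold change, with genes passing the full
#' filter set highlighted.
#'
#' @param object A `taste_de` fit from [run_de()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot taste_de
#' @export
autoplot.taste_de <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$base_mean, y = .data$log2fc,
                                   colour = .data$passes_filters)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "passes filters") +
    ggplot2::labs(x = "mean normalized count",
                  y = expression(log[2] ~ "fold change"),
                  title = "Two-group NB differential expression")
}

#' Plot a calcium trace with its baseline, threshold and detected run
#'
#' @param trace Tibble with `time_s`, `ratio_au`.
#' @param stim_onset_s Stimulus onset (s).
#' @param cfg A [detector_config()].
#' @return A ggplot.
#' @export
plot_trace <- function(trace, stim_onset_s, cfg = detector_config()) {
  base <- compute_baseline(trace, stim_onset_s, cfg)
  call <- detect_response(trace, stim_onset_s, base, cfg)
  p <- ggplot2::ggplot(as_tibble(trace),
                       ggplot2::aes(x = .data$time_s, y = .data$ratio_au)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = call$threshold_au,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_vline(xintercept = stim_onset_s, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "F340/F380 ratio (AU)",
                  title = sprintf("responded: %s (max run %.1f s)",
                                  call$responded, call$max_run_duration_s))
  if (isTRUE(call$responded)) {
    p <- p + ggplot2::annotate("rect", xmin = call$run_start_s,
                               xmax = call$run_end_s, ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "firebrick")
  }
  p
}

#' Plot a gene-body coverage profile
#'
#' @param coverage Tibble from [gene_body_coverage()].
#' @return A ggplot.
#' @export
plot_gene_body_coverage <- function(coverage) {
  ggplot2::ggplot(coverage, ggplot2::aes(x = .data$percentile,
                                         y = .data$coverage_pct)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gene body percentile (5' → 3')",
                  y = "coverage (% of maximum)",
                  title = "Gene-body coverage")
}

#' Plot enrichment results as a ranked bar chart
#'
#' @param results Tibble from [enrich()].
#' @param n_top Number of top-ranked terms to show (default 20).
#' @return A ggplot.
#' @export
plot_enrichment <- function(results, n_top = 20) {
  df <- head(results, n_top)
  lab <- ifelse(is.na(df$term_name), df$term_id, df$term_name)
  df$term <- factor(lab, levels = rev(unique(lab)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$enrichment_score,
                                   y = .data$term,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  title = "Gene-set enrichment (chi-square)")
}
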