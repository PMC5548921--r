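#' Chi-square gene-set enrichment against a background universe
#'
#' For each term, genes are cross-classified by membership in the
#' experimental list versus the rest of the background, and a Pearson
#' chi-square statistic (1 df, no continuity correction) is computed by the
#' closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on the 2x2 table
#'   a = |list ∩ term|,       b = |list \ term|,
#'   c = |(bg \ list) ∩ term|, d = |(bg \ list) \ term|.
#' The comparison column excludes the list by default (no double counting);
#' `inclusive_background = TRUE` compares against the whole background
#' instead. Terms are ranked by the enrichment score `-log10(p)`; terms with
#' `p < p_cutoff` are flagged significant. No multiple-testing correction is
#' applied at this stage by default (the screen is a raw p-value cutoff);
#' `bh = TRUE` adds a BH-adjusted column.
#'
#' @param gene_list Character vector of study genes; must be a subset of
#'   `background`.
#' @param background Character vector, the annotated gene universe.
#' @param annotation Tibble/data frame with columns `term_id`, `term_name`,
#'   `gene_id` (one row per membership). Members outside the background are
#'   ignored; terms left with no members are skipped with a warning.
#' @param p_cutoff Significance screen (default `1e-3`).
#' @param inclusive_background Use the whole background as the comparison
#'   column (default `FALSE`).
#' @param bh Also report BH-adjusted p-values (default `FALSE`).
#' @return Tibble ranked by `enrichment_score`: `term_id`, `term_name`,
#'   `a`, `b`, `c`, `d`, `chi2`, `p_value`, `enrichment_score`, `direction`
#'   (`"over"`/`"under"`), `significant` (and `fdr` when `bh`).
#' @export
enrich <- function(gene_list, background, annotation, p_cutoff = 1e-3,
                   inclusive_background = FALSE, bh = FALSE) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  missing <- setdiff(gene_list, background)
  if (length(missing)) {
    abort(paste0("genes in the list but absent from the background: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ..." else "", "."))
  }
  annotation <- as_tibble(annotation)
  if (!all(c("term_id", "gene_id") %in% names(annotation))) {
    abort("`annotation` needs `term_id` and `gene_id` columns.")
  }
  if (!"term_name" %in% names(annotation)) annotation$term_name <- NA_character_
  all_terms <- unique(annotation$term_id)
  annotation <- annotation[annotation$gene_id %in% background, ]
  annotation <- annotation[!duplicated(annotation[c("term_id", "gene_id")]), ]

  terms <- split(annotation$gene_id, annotation$term_id)
  names_by_term <- annotation$term_name[!duplicated(annotation$term_id)]
  names(names_by_term) <- annotation$term_id[!duplicated(annotation$term_id)]

  empty <- setdiff(all_terms, names(terms))
  if (length(empty)) {
    warn(paste0("skipping terms with no members in the background: ",
                paste(empty, collapse = ", ")))
  }

  n_list <- length(gene_list)
  comparison <- if (inclusive_background) background else setdiff(background, gene_list)
  n_comp <- length(comparison)

  rows <- imap(terms, function(members, id) {
    a <- sum(gene_list %in% members)
    b <- n_list - a
    cc <- sum(comparison %in% members)
    d <- n_comp - cc
    chi2 <- chi_square_2x2(a, b, cc, d)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    tibble(term_id = id,
           term_name = unname(names_by_term[id]),
           a = a, b = b, c = cc, d = d,
           chi2 = chi2, p_value = p,
           enrichment_score = -log10(p),
           direction = if (a / n_list > cc / max(n_comp, 1)) "over" else "under")
  })
  out <- list_rbind(rows)
  out$significant <- out$p_value < p_cutoff
  if (bh) out$fdr <- p.adjust(out$p_value, method = "BH")
  arrange(out, desc(.data$enrichment_score), .data$term_id)
}

#' Closed-form Pearson chi-square for a 2x2 table
#'
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, 1 df, no continuity
#' correction. Degenerate tables (a zero margin) return 0.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return The statistic.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative.")
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(0)
  n * (a * d - b * c)^2 / den
}

#' Collapse redundant terms by member overlap
#'
#' A pragmatic surrogate for semantic-similarity summarization: terms are
#' clustered by single linkage on the Jaccard similarity of their member
#' sets (restricted to the background used for testing), clusters are cut
#' where similarity drops below `gene_overlap_threshold`, and each cluster
#' is represented by its lowest-p term (ties broken lexicographically by
#' `term_id`). Outputs are labelled a surrogate: overlap of annotated genes,
#' not ontology-graph similarity.
#'
#' @param results Tibble from [enrich()].
#' @param annotation The annotation used for testing.
#' @param gene_overlap_threshold Jaccard similarity at or above which terms
#'   merge (default 0.7).
#' @return `results` with `cluster` (integer) and `representative`
#'   (logical) columns, ordered as input.
#' @export
summarize_redundancy <- function(results, annotation,
                                 gene_overlap_threshold = 0.7) {
  if (nrow(results) == 0) {
    results$cluster <- integer(0)
    results$representative <- logical(0)
    return(results)
  }
  annotation <- as_tibble(annotation)
  members <- split(annotation$gene_id, annotation$term_id)
  members <- map(members, unique)
  ids <- results$term_id
  k <- length(ids)
  if (k == 1) {
    results$cluster <- 1L
    results$representative <- TRUE
    return(results)
  }
  sim <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      u <- members[[ids[i]]]
      v <- members[[ids[j]]]
      sim[i, j] <- sim[j, i] <- length(intersect(u, v)) / length(union(u, v))
    }
  }
  tree <- hclust(stats::as.dist(1 - sim), method = "single")
  cl <- cutree(tree, h = 1 - gene_overlap_threshold)
  results$cluster <- unname(cl[ids])
  results$representative <- FALSE
  for (g in unique(results$cluster)) {
    in_cl <- which(results$cluster == g)
    best <- in_cl[order(results$p_value[in_cl], results$term_id[in_cl])][1]
    results$representative[best] <- TRUE
  }
  results
}
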