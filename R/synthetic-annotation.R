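#' Simulate a gene-set (GO-style) annotation with known enriched terms
#'
#' Builds a long annotation table (`term_id`, `term_name`, `gene_id`) over a
#' gene universe. Terms flagged as enriched draw `enriched_excess` of their
#' members from a designated differentially-expressed gene list and the rest
#' uniformly from the remaining universe; non-enriched terms draw uniformly
#' from the whole universe.
#'
#' @param n_terms Number of terms.
#' @param term_size_range Integer range of member counts per term (drawn
#'   uniformly); sizes must be >= 1 and <= the universe size.
#' @param enriched_terms Number of terms (<= `n_terms`) enriched for
#'   `de_genes`.
#' @param gene_universe Character vector of gene identifiers (the
#'   background).
#' @param de_genes Genes the enriched terms over-sample; must be a subset of
#'   `gene_universe`. Required when `enriched_terms > 0`.
#' @param enriched_excess Fraction of an enriched term's members drawn from
#'   `de_genes` (default 0.8).
#' @param seed Integer seed.
#' @return A list with `annotation` (tibble `term_id`, `term_name`,
#'   `gene_id`) and `truth` (tibble `term_id`, `enriched`).
#' @export
simulate_annotation <- function(n_terms, term_size_range = c(10, 100),
                                enriched_terms = 0, gene_universe,
                                de_genes = character(), enriched_excess = 0.8,
                                seed = 1L) {
  if (any(term_size_range < 1)) {
    abort("term sizes must be >= 1 (a term of size 0 is degenerate).")
  }
  if (max(term_size_range) > length(gene_universe)) {
    abort("term sizes cannot exceed the universe size.")
  }
  if (enriched_terms > n_terms) abort("`enriched_terms` must be <= `n_terms`.")
  if (enriched_terms > 0 && length(de_genes) == 0) {
    abort("enriched terms requested but `de_genes` is empty: infeasible.")
  }
  if (!all(de_genes %in% gene_universe)) {
    abort("`de_genes` must be a subset of `gene_universe`.")
  }
  n_de_needed <- ceiling(enriched_excess * max(term_size_range))
  if (enriched_terms > 0 && n_de_needed > length(de_genes)) {
    abort(paste0("requested enrichment is infeasible: up to ", n_de_needed,
                 " members must come from a DE list of length ",
                 length(de_genes), "."))
  }

  with_seed(derive_seed(seed, "annotation"), {
    term_ids <- sprintf("TERM:%04d", seq_len(n_terms))
    enriched <- seq_len(n_terms) <= enriched_terms
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    members <- pmap(list(term_ids, sizes, enriched), function(id, sz, enr) {
      if (enr) {
        n_from_de <- min(ceiling(enriched_excess * sz), length(de_genes))
        from_de <- sample(de_genes, n_from_de)
        rest_pool <- setdiff(gene_universe, from_de)
        c(from_de, sample(rest_pool, sz - n_from_de))
      } else {
        sample(gene_universe, sz)
      }
    })
    annotation <- tibble(
      term_id = rep(term_ids, lengths(members)),
      term_name = rep(paste0("synthetic process ", seq_len(n_terms)),
                      lengths(members)),
      gene_id = unlist(members)
    )
    list(annotation = annotation,
         truth = tibble(term_id = term_ids, enriched = enriched))
  })
}
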