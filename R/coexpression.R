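#' Double-label co-expression counts from the packaged reference table
#'
#' Cell counts from double-label immunostaining of mouse circumvallate
#' papillae: synaptic vesicle components (CPLX2, PCLO) and semaphorin
#' pathway components (SEMA4A, PLEXINB1, CRMP2, FES) against the cell-type
#' markers TAS1R3-GFP (type II), 5HT and GAD1-GFP (type III). The
#' `printed_*` columns carry the percentage strings as originally reported,
#' for comparison against [summarize_coexpression()] output.
#'
#' @return Tibble with columns `panel`, `marker`, `target`, `n_target_pos`,
#'   `n_marker_pos`, `n_double`, `printed_pct_of_target`,
#'   `printed_pct_of_marker`.
#' @export
table2_counts <- function() {
  path <- system.file("extdata", "table2_coexpression_counts.tsv",
                      package = "tastecellseq", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    panel = "c", marker = "c", target = "c",
    n_target_pos = "i", n_marker_pos = "i", n_double = "i",
    printed_pct_of_target = "c", printed_pct_of_marker = "c"))
}

#' Format a co-expression percentage
#'
#' Percentages are truncated (not rounded) toward zero at one decimal,
#' `floor(x * 10) / 10`; values that are exact integers after truncation are
#' rendered without a decimal (`"100"`, `"48"`), others with one
#' (`"94.5"`). The truncated value never exceeds the raw value and differs
#' from it by less than 0.1.
#'
#' @param x Raw percentage(s) in `[0, 100]` (NA allowed).
#' @return Character vector of formatted values (no percent sign).
#' @export
format_coexpression_pct <- function(x) {
  trunc1 <- floor(x * 10 + 1e-9) / 10
  ifelse(is.na(x), NA_character_,
         ifelse(trunc1 == floor(trunc1),
                sprintf("%d", as.integer(round(trunc1))),
                sprintf("%.1f", trunc1)))
}

validate_coexpression_row <- function(row, i = NULL) {
  where <- if (is.null(i)) "" else paste0(" (row ", i, ")")
  vals <- c(row$n_target_pos, row$n_marker_pos, row$n_double)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    abort(paste0("cell counts must be non-negative integers", where, "."))
  }
  if (row$n_double > min(row$n_target_pos, row$n_marker_pos)) {
    abort(paste0("n_double exceeds a single-label count", where, ": ",
                 row$n_double, " > min(", row$n_target_pos, ", ",
                 row$n_marker_pos, ")."))
  }
  invisible(row)
}

#' Summarize double-label co-expression counts
#'
#' For each row of counts, computes the percentage of target-positive cells
#' that are also marker-positive (`pct_of_target = 100 n_double /
#' n_target_pos`) and the percentage of marker-positive cells that are also
#' target-positive (`pct_of_marker = 100 n_double / n_marker_pos`), with
#' formatted strings per [format_coexpression_pct()]. A zero denominator
#' yields an `NA` percentage and sets `undefined = TRUE` rather than
#' failing.
#'
#' @param counts Tibble/data frame with columns `marker`, `target`,
#'   `n_target_pos`, `n_marker_pos`, `n_double` (one or more rows).
#' @return Tibble, one row per input row, adding `pct_of_target`,
#'   `pct_of_marker`, `fmt_pct_of_target`, `fmt_pct_of_marker`,
#'   `ratio_of_target`, `ratio_of_marker`, `undefined`.
#' @export
summarize_coexpression <- function(counts) {
  counts <- as_tibble(counts)
  needed <- c("marker", "target", "n_target_pos", "n_marker_pos", "n_double")
  if (!all(needed %in% names(counts))) {
    abort(paste0("`counts` needs columns ", paste(needed, collapse = ", "), "."))
  }
  if (nrow(counts) == 0) {
    out <- counts
    out$pct_of_target <- out$pct_of_marker <- numeric(0)
    out$fmt_pct_of_target <- out$fmt_pct_of_marker <- character(0)
    out$ratio_of_target <- out$ratio_of_marker <- character(0)
    out$undefined <- logical(0)
    return(out)
  }
  for (i in seq_len(nrow(counts))) {
    validate_coexpression_row(counts[i, ], i)
  }
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  counts$pct_of_target <- pct(counts$n_double, counts$n_target_pos)
  counts$pct_of_marker <- pct(counts$n_double, counts$n_marker_pos)
  counts$fmt_pct_of_target <- format_coexpression_pct(counts$pct_of_target)
  counts$fmt_pct_of_marker <- format_coexpression_pct(counts$pct_of_marker)
  counts$ratio_of_target <- sprintf("%d/%d", counts$n_double,
                                    counts$n_target_pos)
  counts$ratio_of_marker <- sprintf("%d/%d", counts$n_double,
                                    counts$n_marker_pos)
  counts$undefined <- counts$n_target_pos == 0 | counts$n_marker_pos == 0
  counts
}
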