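#' Read and write genes-by-cells count matrices
#'
#' Two on-disk formats are supported: TSV (first column `gene_id`, one column
#' per cell) and MatrixMarket (`matrix.mtx` plus `genes.tsv` / `cells.tsv`
#' sidecars holding the row and column identifiers, one per line). Reading
#' validates that entries are finite non-negative integers and identifiers
#' are unique; the round trip `read_counts(write_counts(x))` is lossless.
#'
#' @param path For TSV, the file; for MTX, the `.mtx` file (sidecars are
#'   looked up next to it as `genes.tsv` and `cells.tsv`).
#' @param format `"tsv"` or `"mtx"` (default: guessed from the extension).
#' @return `read_counts()` returns an integer matrix with gene rownames and
#'   cell colnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    if (names(df)[1] != "gene_id") {
      abort("count TSV must have `gene_id` as its first column.")
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
  } else {
    m <- as.matrix(Matrix::readMM(path))
    side <- function(f) file.path(dirname(path), f)
    rownames(m) <- readr::read_lines(side("genes.tsv"))
    colnames(m) <- readr::read_lines(side("cells.tsv"))
  }
  m <- validate_counts_values(m)
  m
}

validate_counts_values <- function(m) {
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(paste0("counts must be finite non-negative integers; first offence ",
                 "at gene ", rownames(m)[bad[1, 1]], ", cell ",
                 colnames(m)[bad[1, 2]], "."))
  }
  dups <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dups)) {
    abort(paste0("duplicate gene_id in counts file: ",
                 paste(dups, collapse = ", "), "."))
  }
  if (anyDuplicated(colnames(m))) abort("duplicate cell identifiers.")
  storage.mode(m) <- "integer"
  invisible(m)
}

#' @rdname read_counts
#' @param counts Integer matrix, genes x cells, with dimnames.
#' @export
write_counts <- function(counts, path, format = c("auto", "tsv", "mtx")) {
  assert_count_matrix(counts)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    df <- as_tibble(counts, rownames = "gene_id")
    readr::write_tsv(df, path)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    side <- function(f) file.path(dirname(path), f)
    readr::write_lines(rownames(counts), side("genes.tsv"))
    readr::write_lines(colnames(counts), side("cells.tsv"))
  }
  invisible(path)
}

#' Drop genes with zero counts in every cell
#'
#' Genes not observed in any library carry no information for normalization
#' or testing and are removed up front.
#'
#' @param counts Integer matrix, genes x cells.
#' @return The matrix restricted to genes with at least one nonzero count,
#'   with attribute `n_retained`.
#' @export
drop_all_zero_genes <- function(counts) {
  assert_count_matrix(counts)
  keep <- rowSums(counts) > 0
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  out
}
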