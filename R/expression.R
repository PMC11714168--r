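#' Read a gene-expression matrix
#'
#' Reads a delimited genes x samples table: first column gene symbols,
#' header row sample identifiers, numeric body. Values are expected on a
#' non-negative log-like scale (e.g. log2(TPM+1) or log2(FPKM+1)).
#' Duplicate gene rows are collapsed by keeping the row with the highest
#' mean expression (deterministic; first occurrence wins ties).
#'
#' @param path file path (plain text or gzip).
#' @param delimiter field separator; `"\t"` (default) or `","`.
#' @return numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path))
    stop("expression file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          quote = "", comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression table needs a gene column plus >=1 sample column",
         call. = FALSE)
  genes <- as.character(df[[1]])
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(as.numeric(body))
  bad_cells <- which(is.na(vals))
  if (length(bad_cells)) {
    bad <- bad_cells[1]
    r <- ((bad - 1) %% nrow(body)) + 1
    cl <- ((bad - 1) %/% nrow(body)) + 1
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' (value '%s')",
                 genes[r], colnames(body)[cl], body[bad]), call. = FALSE)
  }
  mat <- matrix(vals, nrow = nrow(body),
                dimnames = list(genes, colnames(body)))
  mat <- collapse_duplicate_genes(mat)
  validate_expression(mat)
  mat
}

# keep, for each duplicated symbol, the row with the highest mean
collapse_duplicate_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  means <- rowMeans(mat)
  ord <- order(factor(rownames(mat), levels = unique(rownames(mat))),
               -means)
  mat <- mat[ord, , drop = FALSE]
  mat[!duplicated(rownames(mat)), , drop = FALSE]
}

#' Validate an expression matrix
#'
#' Checks the expression-matrix contract: numeric matrix with unique,
#' non-empty gene and sample names, all values finite and non-negative,
#' at least one gene and one sample.
#'
#' @param mat numeric matrix, genes x samples.
#' @return `mat`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression must be a numeric matrix", call. = FALSE)
  if (nrow(mat) < 1L || ncol(mat) < 1L)
    stop("expression matrix needs >=1 gene and >=1 sample", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  if (any(!is.finite(mat)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  if (any(mat < 0))
    stop("negative expression values found; supply log-normalized ",
         "non-negative values such as log2(TPM+1)", call. = FALSE)
  invisible(mat)
}

#' Filter genes by cohort prevalence
#'
#' Retains genes expressed (value strictly greater than
#' `expressed_threshold`) in at least `min_fraction` of the samples. The
#' defaults implement the standard cohort filter: genes expressed in at
#' least 50% of samples are kept.
#'
#' @param expr genes x samples numeric matrix.
#' @param min_fraction minimum fraction of samples, in (0, 1].
#' @param expressed_threshold value above which a gene counts as expressed
#'   in a sample (default 0, on the log scale).
#' @return filtered expression matrix (same samples, fewer or equal genes).
#' @export
filter_genes_by_prevalence <- function(expr, min_fraction = 0.5,
                                       expressed_threshold = 0) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  validate_expression(expr)
  frac <- rowMeans(expr > expressed_threshold)
  keep <- frac >= min_fraction
  if (!any(keep))
    stop("prevalence filter removed every gene; lower `min_fraction` or ",
         "`expressed_threshold`", call. = FALSE)
  expr[keep, , drop = FALSE]
}

#' Write an expression matrix
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delimiter = "\t") {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
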