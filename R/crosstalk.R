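#' Jaccard matrix between two gene-set collections
#'
#' Entry (C, G) is |C intersect G| / |C union G|, the Jaccard coefficient
#' between cell signature C and GO term G; 0 when the sets are disjoint.
#' Both collections should first be restricted to a common measured-gene
#' universe ([restrict_to_universe()]) so that overlap and median expression
#' are computed over the same genes. The matrix depends only on the gene
#' sets, not on any sample, so it is computed once per cohort.
#'
#' @param cells cell-signature `gene_set_collection` (rows).
#' @param gos GO-BP `gene_set_collection` (columns).
#' @return cells x go_terms numeric matrix in [0, 1].
#' @export
jaccard_matrix <- function(cells, gos) {
  if (!length(cells) || !length(gos))
    stop("both collections must be non-empty", call. = FALSE)
  idx <- overlap_index(cells, gos)
  n_int <- matrix(lengths(idx$overlap), nrow = length(cells),
                  dimnames = list(names(cells), names(gos)))
  n_c <- lengths(cells$sets)
  n_g <- lengths(gos$sets)
  n_union <- outer(n_c, n_g, `+`) - n_int
  J <- ifelse(n_union > 0, n_int / n_union, 0)
  dimnames(J) <- list(names(cells), names(gos))
  J
}

# Precompute, for every (cell, GO) pair, the integer positions (within a
# fixed gene ordering) of the shared genes. This is the per-cohort cache:
# only the median expression over these positions varies per sample.
# Returns list(overlap = list column-major over pairs, genes = ordering).
overlap_index <- function(cells, gos) {
  genes <- unique(c(unlist(cells$sets, use.names = FALSE),
                    unlist(gos$sets, use.names = FALSE)))
  cell_idx <- lapply(cells$sets, function(g) match(g, genes))
  go_idx <- lapply(gos$sets, function(g) match(g, genes))
  membership <- matrix(FALSE, nrow = length(genes), ncol = length(cells))
  for (i in seq_along(cell_idx)) membership[cell_idx[[i]], i] <- TRUE
  overlap <- vector("list", length(cells) * length(gos))
  k <- 0L
  for (j in seq_along(go_idx)) {
    gj <- go_idx[[j]]
    for (i in seq_along(cell_idx)) {
      k <- k + 1L
      overlap[[k]] <- gj[membership[gj, i]]
    }
  }
  list(overlap = overlap, genes = genes,
       n_cells = length(cells), n_gos = length(gos))
}

#' Median expression of shared genes, per cell-GO pair
#'
#' Entry (C, G) is the median, within one sample, of the expression of the
#' genes shared by cell set C and GO set G (the GEP_med term of the
#' bipartite edge weight); 0 when the overlap is empty. Even-sized overlaps
#' use the midpoint-average median.
#'
#' @param cells,gos gene-set collections restricted to the expression
#'   universe.
#' @param expr_column named numeric vector: one sample's expression, indexed
#'   by gene symbol, covering every gene in the collections.
#' @param index optional precomputed [overlap_index()] cache (cohort reuse).
#' @return cells x go_terms numeric matrix of median expression values.
#' @export
median_overlap_expression <- function(cells, gos, expr_column, index = NULL) {
  if (is.null(index)) index <- overlap_index(cells, gos)
  missing_genes <- setdiff(index$genes, names(expr_column))
  if (length(missing_genes))
    stop("gene(s) in a set but absent from the expression vector (was ",
         "restrict_to_universe() skipped?): ",
         paste(utils::head(missing_genes, 5), collapse = ", "),
         call. = FALSE)
  ev <- as.numeric(expr_column[index$genes])
  med <- vapply(index$overlap, function(pos) {
    if (!length(pos)) 0 else stats::median(ev[pos])
  }, numeric(1))
  matrix(med, nrow = index$n_cells,
         dimnames = list(names(cells), names(gos)))
}

#' Bipartite cell-GO edge weights for one sample
#'
#' The edge weight between cell C and GO term G is
#' W = J(C, G) * median expression of the shared genes: set overlap scaled
#' by how active the shared genes are in this sample.
#'
#' @param J Jaccard matrix from [jaccard_matrix()].
#' @param M median-expression matrix from [median_overlap_expression()],
#'   same dimensions and dimname order as `J`.
#' @param sample_id sample identifier attached to the result.
#' @return object of class `bipartite_weights`: list with `W` (cells x
#'   go_terms matrix), `cells`, `go_terms`, `sample_id`.
#' @export
bipartite_weights <- function(J, M, sample_id = "sample") {
  if (!identical(dim(J), dim(M)))
    stop("J and M must have identical dimensions", call. = FALSE)
  if (!identical(dimnames(J), dimnames(M)))
    stop("J and M must have identical dimnames (same row/column order)",
         call. = FALSE)
  structure(list(W = J * M,
                 cells = rownames(J), go_terms = colnames(J),
                 sample_id = sample_id),
            class = "bipartite_weights")
}

#' Project bipartite weights to the cell-cell crosstalk adjacency
#'
#' One-mode projection of the cell-GO bipartite network: the crosstalk
#' weight between cells i and j is the sum over shared GO terms of the
#' products of their bipartite edge weights,
#' R[i, j] = sum_k W[i, k] * W[j, k], i.e. R = W W^T. The diagonal is set
#' to 0 (no self-crosstalk); two cells sharing no GO term get weight 0.
#'
#' @param bw a `bipartite_weights` object.
#' @return object of class `crosstalk_matrix`: list with `R` (symmetric
#'   cells x cells matrix, zero diagonal), `cells`, `sample_id`.
#' @export
crosstalk_adjacency <- function(bw) {
  stopifnot(inherits(bw, "bipartite_weights"))
  R <- tcrossprod(bw$W)
  # enforce exact symmetry against float summation-order effects
  R <- (R + t(R)) / 2
  diag(R) <- 0
  structure(list(R = R, cells = bw$cells, sample_id = bw$sample_id),
            class = "crosstalk_matrix")
}

#' @export
print.crosstalk_matrix <- function(x, ...) {
  nz <- sum(x$R[upper.tri(x$R)] > 0)
  cat(sprintf("crosstalk_matrix: %d cells, %d positive edges (sample '%s')\n",
              length(x$cells), nz, x$sample_id))
  invisible(x)
}

#' Export a crosstalk network as an edge list
#' @param ct a `crosstalk_matrix`.
#' @param path output TSV path (columns cell_i, cell_j, weight); only
#'   upper-triangle edges with positive weight are written.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(ct, path) {
  stopifnot(inherits(ct, "crosstalk_matrix"))
  ut <- which(upper.tri(ct$R) & ct$R > 0, arr.ind = TRUE)
  df <- data.frame(cell_i = ct$cells[ut[, 1]],
                   cell_j = ct$cells[ut[, 2]],
                   weight = ct$R[ut],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
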