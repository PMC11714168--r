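#' Raw infiltration scores for a single sample
#'
#' Composes the full per-sample chain: Jaccard x median-expression bipartite
#' weights, projection to the cell-cell crosstalk adjacency, and restarted
#' random-walk centrality. Returns the raw stationary scores (pre-log,
#' pre-normalization), which sum to 1 across cells.
#'
#' @param expr_column named numeric vector, one sample's expression indexed
#'   by gene symbol.
#' @param cells,gos gene-set collections restricted to the expression
#'   universe (see [restrict_to_universe()]).
#' @param cfg an [rwr_config()].
#' @param J optional precomputed [jaccard_matrix()] (cohort reuse).
#' @param index optional precomputed overlap cache (cohort reuse).
#' @param sample_id identifier used in the returned objects.
#' @return named numeric vector of raw per-cell scores (sum 1).
#' @export
compute_inscore_sample <- function(expr_column, cells, gos,
                                   cfg = rwr_config(), J = NULL,
                                   index = NULL, sample_id = "sample") {
  if (is.null(index)) index <- overlap_index(cells, gos)
  if (is.null(J)) J <- jaccard_matrix(cells, gos)
  M <- median_overlap_expression(cells, gos, expr_column, index = index)
  bw <- bipartite_weights(J, M, sample_id = sample_id)
  ct <- crosstalk_adjacency(bw)
  cv <- rwr_stationary(ct, cfg)
  if (!cv$converged)
    warning("sample '", sample_id, "': random walk not converged")
  cv$scores
}

#' Cohort infiltration-score matrix
#'
#' Runs the per-sample network pipeline for every sample of a cohort and
#' assembles the cells x samples InScore matrix. Per sample, raw stationary
#' scores (which follow a power-law-like distribution) are log10-transformed
#' and then min-max normalized within the sample so every column spans
#' [0, 1]:  InScore = (s - min s) / (max s - min s)  with s = log10(raw).
#' A constant column (all cells tied, e.g. a single-cell network) maps to
#' 0.5 everywhere, with a warning. Columns are processed independently, so
#' a sample's scores do not depend on which other samples are present.
#'
#' Scores are designed for comparing cell types within and across samples
#' after the within-sample normalization; they are relative infiltration
#' levels, not absolute cell fractions.
#'
#' @param expr genes x samples numeric matrix (validated, prevalence
#'   filtering already applied if desired).
#' @param cells,gos gene-set collections; restricted to `rownames(expr)`
#'   automatically unless `restrict = FALSE`.
#' @param cfg an [rwr_config()].
#' @param restrict intersect the collections with the measured genes first
#'   (default `TRUE`; disable only for sensitivity analysis).
#' @param keep_raw also return the raw stationary scores.
#' @return object of class `inscore_matrix`: list with `scores` (cells x
#'   samples matrix in [0, 1]), `cells`, `samples`, and `raw` (if
#'   `keep_raw`).
#' @export
compute_inscore_cohort <- function(expr, cells, gos, cfg = rwr_config(),
                                   restrict = TRUE, keep_raw = FALSE) {
  validate_expression(expr)
  if (restrict) {
    cells <- restrict_to_universe(cells, rownames(expr))
    gos <- restrict_to_universe(gos, rownames(expr))
  }
  if (!length(cells) || !length(gos))
    stop("no gene set survives restriction to the expression universe",
         call. = FALSE)
  index <- overlap_index(cells, gos)
  J <- jaccard_matrix(cells, gos)
  raw <- vapply(colnames(expr), function(s)
    compute_inscore_sample(expr[, s], cells, gos, cfg,
                           J = J, index = index, sample_id = s),
    numeric(length(cells)))
  raw <- matrix(raw, nrow = length(cells),
                dimnames = list(names(cells), colnames(expr)))
  if (any(raw <= 0))
    stop("internal contract violation: non-positive raw score", call. = FALSE)
  scores <- apply(raw, 2, normalize_log_minmax)
  scores <- matrix(scores, nrow = nrow(raw), dimnames = dimnames(raw))
  out <- list(scores = scores, cells = rownames(raw),
              samples = colnames(raw))
  if (keep_raw) out$raw <- raw
  structure(out, class = "inscore_matrix")
}

# log10 then min-max to [0,1]; constant column -> 0.5 (warned)
normalize_log_minmax <- function(raw) {
  s <- log10(raw)
  rng <- range(s)
  if (rng[1] == rng[2]) {
    warning("constant score column; normalized values set to 0.5")
    return(rep(0.5, length(s)))
  }
  (s - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.inscore_matrix <- function(x, ...) {
  cat(sprintf("inscore_matrix: %d cells x %d samples, values in [%g, %g]\n",
              length(x$cells), length(x$samples),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Write an InScore matrix as TSV
#' @param inscores an `inscore_matrix`.
#' @param path output path; rows = cells, columns = samples.
#' @return `path`, invisibly.
#' @export
write_inscore <- function(inscores, path) {
  stopifnot(inherits(inscores, "inscore_matrix"))
  df <- data.frame(cell = inscores$cells, inscores$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate a linear (CT-TME style) risk score
#'
#' Computes, per sample, the linear combination sum_k beta_k * InScore_k of
#' selected cells' infiltration scores. Coefficients are user-supplied
#' (typically from an external survival model fit); this function only
#' evaluates the linear combination.
#'
#' @param inscores an `inscore_matrix`.
#' @param model data frame with columns `cell` and `beta` (distinct cells,
#'   finite coefficients).
#' @return named numeric vector of per-sample risk scores.
#' @export
ct_tme_score <- function(inscores, model) {
  stopifnot(inherits(inscores, "inscore_matrix"))
  if (!is.data.frame(model) || !all(c("cell", "beta") %in% names(model)))
    stop("`model` must be a data frame with columns `cell` and `beta`",
         call. = FALSE)
  if (anyDuplicated(model$cell))
    stop("duplicate cell names in model", call. = FALSE)
  if (any(!is.finite(model$beta)))
    stop("non-finite coefficient(s) in model", call. = FALSE)
  missing_cells <- setdiff(model$cell, inscores$cells)
  if (length(missing_cells))
    stop("model cell(s) absent from InScore matrix: ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  drop(crossprod(inscores$scores[model$cell, , drop = FALSE], model$beta))
}

#' Read model coefficients from a two-column TSV
#' @param path TSV with header columns `cell` and `beta` (or two unnamed
#'   columns in that order).
#' @return data frame with columns `cell`, `beta`.
#' @export
read_ct_tme_model <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("cell", "beta") %in% names(df))) {
    df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                            stringsAsFactors = FALSE)
    names(df)[1:2] <- c("cell", "beta")
  }
  df$beta <- as.numeric(df$beta)
  df[, c("cell", "beta")]
}
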