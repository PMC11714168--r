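#' Specification for a synthetic validation cohort
#'
#' Describes a fully self-contained synthetic data set: a gene universe,
#' cell-signature and GO-BP collections with controlled overlap, and a
#' log-scale expression cohort in which chosen cell types' exclusive
#' signature genes are up-shifted by a known effect size. Used to test
#' every pipeline stage against known ground truth.
#'
#' Baseline expression is drawn log-normal on the measurement scale
#' (`rlnorm(meanlog, sdlog)`), emulating log2(TPM+1)-like values; defaults
#' (1.0, 0.5) give a typical bulk-like right-skewed non-negative profile.
#' A spike adds `delta` to the designated cell's exclusive signature genes
#' (genes belonging to exactly one cell set, so ground truth is
#' unambiguous) in the designated sample.
#'
#' @param n_genes size of the gene universe.
#' @param n_cells number of cell-signature sets.
#' @param n_go number of GO-BP sets.
#' @param genes_per_cell length-2 range of signature sizes; the default
#'   (15-40) keeps signatures inside the 15-350 set-size band the method
#'   operates on.
#' @param genes_per_go length-2 range of GO set sizes.
#' @param overlap_rate probability that a GO gene is drawn from the pooled
#'   signature genes rather than the whole universe, in [0, 1].
#' @param n_samples cohort size.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   expression.
#' @param spike data frame with columns `cell`, `sample`, `delta`
#'   (additive log-expression shift, >= 0), or `NULL`.
#' @param seed integer RNG seed; the generator is reproducible given it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 500L, n_cells = 12L, n_go = 40L,
                           genes_per_cell = c(15L, 40L),
                           genes_per_go = c(15L, 40L),
                           overlap_rate = 0.5, n_samples = 6L,
                           baseline_meanlog = 1.0, baseline_sdlog = 0.5,
                           spike = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, n_cells >= 1, n_go >= 1, n_samples >= 1,
            length(genes_per_cell) == 2, length(genes_per_go) == 2,
            overlap_rate >= 0, overlap_rate <= 1)
  if (max(genes_per_cell) > n_genes || max(genes_per_go) > n_genes)
    stop("set size range exceeds the gene universe", call. = FALSE)
  if (!is.null(spike)) {
    stopifnot(is.data.frame(spike),
              all(c("cell", "sample", "delta") %in% names(spike)))
    if (any(spike$delta < 0))
      stop("spike effect `delta` must be >= 0", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells), n_go = as.integer(n_go),
                 genes_per_cell = as.integer(genes_per_cell),
                 genes_per_go = as.integer(genes_per_go),
                 overlap_rate = overlap_rate,
                 n_samples = as.integer(n_samples),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 spike = spike, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic cohort
#'
#' Draws gene sets and an expression cohort according to a
#' [synthetic_spec()]. Cell signatures are sampled independently from the
#' universe (overlap between signatures arises naturally); GO sets mix
#' pooled signature genes (probability `overlap_rate`) with background
#' genes. When `overlap_rate > 0`, resampling (bounded retries) guarantees
#' every cell shares at least one gene with at least one GO term and has at
#' least one exclusive gene. Spikes add `delta` to the target cell's
#' exclusive signature genes in the target sample.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `expr` (genes x samples matrix), `cells` and `gos`
#'   (gene-set collections), and `truth` (data frame: cell, sample, delta,
#'   n_exclusive_genes; zero rows when no spike).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  universe <- sprintf("g%05d", seq_len(spec$n_genes))
  cell_names <- sprintf("cell_%02d", seq_len(spec$n_cells))
  go_names <- sprintf("GO_SYN_%04d", seq_len(spec$n_go))

  for (attempt in seq_len(50L)) {
    cell_sets <- lapply(seq_len(spec$n_cells), function(i) {
      k <- sample(spec$genes_per_cell[1]:spec$genes_per_cell[2], 1)
      sample(universe, k)
    })
    names(cell_sets) <- cell_names
    pooled <- unlist(cell_sets, use.names = FALSE)
    exclusive_ok <- all(vapply(cell_sets, function(g)
      any(table(pooled)[g] == 1L), logical(1)))

    # overlap_rate = 0 must yield GO sets disjoint from every signature
    background <- if (spec$overlap_rate == 0)
      setdiff(universe, pooled) else universe
    if (!length(background))
      stop("gene universe too small for disjoint GO sets", call. = FALSE)
    go_sets <- lapply(seq_len(spec$n_go), function(j) {
      k <- sample(spec$genes_per_go[1]:spec$genes_per_go[2], 1)
      from_sig <- stats::rbinom(1, k, spec$overlap_rate)
      from_sig <- min(from_sig, length(unique(pooled)))
      unique(c(if (from_sig > 0) sample(unique(pooled), from_sig),
               sample(background, min(k - from_sig, length(background)))))
    })
    names(go_sets) <- go_names

    if (spec$overlap_rate > 0) {
      go_union <- unique(unlist(go_sets, use.names = FALSE))
      coverage_ok <- all(vapply(cell_sets, function(g)
        any(g %in% go_union), logical(1)))
    } else coverage_ok <- TRUE
    if (coverage_ok && exclusive_ok) break
    if (attempt == 50L)
      stop("could not satisfy overlap/exclusivity constraints in 50 ",
           "attempts; relax the spec", call. = FALSE)
  }

  sample_names <- sprintf("s%02d", seq_len(spec$n_samples))
  expr <- matrix(stats::rlnorm(spec$n_genes * spec$n_samples,
                               spec$baseline_meanlog, spec$baseline_sdlog),
                 nrow = spec$n_genes,
                 dimnames = list(universe, sample_names))

  pooled <- unlist(cell_sets, use.names = FALSE)
  counts <- table(pooled)
  truth <- data.frame(cell = character(0), sample = character(0),
                      delta = numeric(0), n_exclusive_genes = integer(0),
                      stringsAsFactors = FALSE)
  if (!is.null(spec$spike) && nrow(spec$spike)) {
    for (i in seq_len(nrow(spec$spike))) {
      cl <- as.character(spec$spike$cell[i])
      sm <- as.character(spec$spike$sample[i])
      dl <- spec$spike$delta[i]
      if (!cl %in% cell_names)
        stop("spike cell not in generated collection: ", cl, call. = FALSE)
      if (!sm %in% sample_names)
        stop("spike sample not in generated cohort: ", sm, call. = FALSE)
      excl <- cell_sets[[cl]][counts[cell_sets[[cl]]] == 1L]
      expr[excl, sm] <- expr[excl, sm] + dl
      truth <- rbind(truth, data.frame(
        cell = cl, sample = sm, delta = dl,
        n_exclusive_genes = length(excl), stringsAsFactors = FALSE))
    }
  }

  list(expr = expr,
       cells = gene_set_collection(cell_sets, kind = "cell_signature"),
       gos = gene_set_collection(go_sets, kind = "go_bp"),
       truth = truth)
}

#' Write a synthetic cohort as pipeline-ready files
#'
#' Writes the expression matrix (TSV), both collections (GMT), and the
#' ground-truth spike table into a directory, in exactly the formats the
#' main pipeline reads.
#'
#' @param fixture result of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_synthetic <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             cells = file.path(dir, "cell_signatures.gmt"),
             gos = file.path(dir, "go_bp.gmt"),
             truth = file.path(dir, "spike_truth.tsv"))
  write_expression(fixture$expr, paths["expression"])
  write_gmt(fixture$cells, paths["cells"])
  write_gmt(fixture$gos, paths["gos"])
  utils::write.table(fixture$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
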