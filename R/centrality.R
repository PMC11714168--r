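#' Random-walk-with-restart configuration
#'
#' The infiltration score of a cell is the limiting (stationary)
#' distribution of a random walk over the weighted crosstalk network with
#' uniform restarts: at each step the walker restarts at a uniformly chosen
#' cell with probability `restart_prob`, otherwise moves along an edge with
#' probability proportional to its weight. The limit is computed by
#' deterministic fixed-point iteration (no simulation, no seed).
#'
#' @param restart_prob restart probability in (0, 1]; default 0.15, the
#'   conventional damping complement. Infiltration scores are relative, and
#'   ranks are stable over a broad range of this parameter.
#' @param tol L1 convergence threshold (default 1e-10).
#' @param max_iter maximum iterations (default 1000).
#' @param dangling_policy what a walker at an isolated (zero-degree) cell
#'   does: `"uniform_redistribute"` (default) jumps uniformly to any cell,
#'   keeping every score positive; `"self_restart"` drops through to the
#'   restart term only.
#' @return object of class `rwr_config`.
#' @export
rwr_config <- function(restart_prob = 0.15, tol = 1e-10, max_iter = 1000L,
                       dangling_policy = c("uniform_redistribute",
                                           "self_restart")) {
  dangling_policy <- match.arg(dangling_policy)
  stopifnot(restart_prob > 0, restart_prob <= 1, tol > 0, max_iter >= 1)
  structure(list(restart_prob = restart_prob, tol = tol,
                 max_iter = as.integer(max_iter),
                 dangling_policy = dangling_policy),
            class = "rwr_config")
}

#' Column-stochastic transition matrix of a crosstalk network
#'
#' Column j is R[, j] scaled to sum 1 (the walker leaves cell j along edges
#' with probability proportional to their weights). A zero-degree column is
#' replaced according to the dangling policy: `uniform_redistribute` puts
#' 1/n in every entry; `self_restart` leaves it all-zero (the walker's mass
#' re-enters via the restart term only).
#'
#' @param ct a `crosstalk_matrix` (or a plain symmetric non-negative matrix
#'   with zero diagonal).
#' @param dangling_policy see [rwr_config()].
#' @return cells x cells column-stochastic matrix.
#' @export
transition_matrix <- function(ct, dangling_policy = c("uniform_redistribute",
                                                      "self_restart")) {
  dangling_policy <- match.arg(dangling_policy)
  R <- if (inherits(ct, "crosstalk_matrix")) ct$R else ct
  n <- nrow(R)
  deg <- colSums(R)
  P <- R
  pos <- deg > 0
  if (any(pos))
    P[, pos] <- sweep(R[, pos, drop = FALSE], 2, deg[pos], `/`)
  if (any(!pos))
    P[, !pos] <- if (dangling_policy == "uniform_redistribute") 1 / n else 0
  P
}

#' Stationary distribution of the restarted random walk
#'
#' Iterates pi <- r*u + (1-r) * P %*% pi from the uniform vector
#' u = 1/n until the L1 change falls below `cfg$tol` or `cfg$max_iter` is
#' reached, then normalizes to sum 1. Every score is strictly positive when
#' `restart_prob > 0`.
#'
#' @param ct a `crosstalk_matrix` (or plain matrix, see
#'   [transition_matrix()]).
#' @param cfg an [rwr_config()].
#' @return object of class `centrality_vector`: list with `cells`, `scores`
#'   (named, positive, sum 1), `iterations_used`, `converged`.
#' @export
rwr_stationary <- function(ct, cfg = rwr_config()) {
  stopifnot(inherits(cfg, "rwr_config"))
  cells <- if (inherits(ct, "crosstalk_matrix")) ct$cells else rownames(ct)
  P <- transition_matrix(ct, cfg$dangling_policy)
  n <- nrow(P)
  if (is.null(cells)) cells <- paste0("cell", seq_len(n))
  r <- cfg$restart_prob
  u <- rep(1 / n, n)
  pi_t <- u
  converged <- FALSE
  iter <- 0L
  if (r == 1) {
    # pure restart: limiting distribution is exactly uniform
    converged <- TRUE
  } else {
    for (iter in seq_len(cfg$max_iter)) {
      pi_next <- r * u + (1 - r) * drop(P %*% pi_t)
      if (sum(abs(pi_next - pi_t)) < cfg$tol) {
        pi_t <- pi_next
        converged <- TRUE
        break
      }
      pi_t <- pi_next
    }
    if (!converged)
      warning(sprintf(
        "random walk did not converge in %d iterations (L1 tol %g)",
        cfg$max_iter, cfg$tol))
  }
  pi_t <- pi_t / sum(pi_t)
  structure(list(cells = cells,
                 scores = stats::setNames(pi_t, cells),
                 iterations_used = iter, converged = converged),
            class = "centrality_vector")
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat(sprintf(
    "centrality_vector: %d cells, %d iteration(s), converged = %s\n",
    length(x$cells), x$iterations_used, x$converged))
  invisible(x)
}
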