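# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the package's vectorized/factorized code paths:
# plain set arithmetic, explicit loops, and a dense linear solve.

jaccard_brute <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 0 else length(intersect(a, b)) / u
}

# cells/gos: named lists of character vectors; ev: named expression vector
bipartite_brute <- function(cells, gos, ev) {
  W <- matrix(0, length(cells), length(gos),
              dimnames = list(names(cells), names(gos)))
  for (i in names(cells)) for (j in names(gos)) {
    ov <- intersect(cells[[i]], gos[[j]])
    med <- if (length(ov)) stats::median(unname(ev[ov])) else 0
    W[i, j] <- jaccard_brute(cells[[i]], gos[[j]]) * med
  }
  W
}

# triple-loop one-mode projection with zero diagonal
crosstalk_brute <- function(W) {
  n <- nrow(W)
  R <- matrix(0, n, n, dimnames = list(rownames(W), rownames(W)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (k in seq_len(ncol(W))) s <- s + W[i, k] * W[j, k]
    R[i, j] <- s
  }
  R
}

# closed-form stationary distribution: pi = r (I - (1-r) P)^-1 u
rwr_solve <- function(R, restart_prob,
                      dangling_policy = "uniform_redistribute") {
  n <- nrow(R)
  P <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- sum(R[, j])
    if (d > 0) P[, j] <- R[, j] / d
    else if (dangling_policy == "uniform_redistribute") P[, j] <- 1 / n
  }
  u <- rep(1 / n, n)
  pi_vec <- solve(diag(n) - (1 - restart_prob) * P, restart_prob * u)
  pi_vec / sum(pi_vec)
}

# fixed worked example: 3 cells, 2 GO terms, one sample
toy_fixture <- function() {
  cells <- list(A = c("g1", "g2", "g3"),
                B = c("g2", "g3", "g4"),
                C = c("g5", "g6"))
  gos <- list(GO1 = c("g1", "g2"),
              GO2 = c("g3", "g4", "g5"))
  ev <- c(g1 = 2, g2 = 4, g3 = 1, g4 = 3, g5 = 5, g6 = 0.5)
  list(cells = gene_set_collection(cells, kind = "cell_signature"),
       gos = gene_set_collection(gos, kind = "go_bp"),
       cell_list = cells, go_list = gos, ev = ev)
}

# random symmetric non-negative adjacency with zero diagonal
random_adjacency <- function(n, p_edge = 0.7) {
  R <- matrix(0, n, n)
  up <- upper.tri(R)
  w <- stats::runif(sum(up))
  w[stats::runif(sum(up)) > p_edge] <- 0
  R[up] <- w
  R <- R + t(R)
  dimnames(R) <- list(paste0("c", seq_len(n)), paste0("c", seq_len(n)))
  R
}

write_gmt_lines <- function(lines) {
  path <- tempfile("sets", fileext = ".gmt")
  writeLines(lines, path)
  path
}
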