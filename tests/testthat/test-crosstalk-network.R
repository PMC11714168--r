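test_that("jaccard_matrix matches brute-force set arithmetic", {
  toy <- toy_fixture()
  J <- jaccard_matrix(toy$cells, toy$gos)
  expect_equal(J["A", "GO1"], 2 / 3)            # {g1,g2} over {g1,g2,g3}
  for (i in names(toy$cell_list)) for (j in names(toy$go_list))
    expect_equal(J[i, j], jaccard_brute(toy$cell_list[[i]],
                                        toy$go_list[[j]]))
  # identity and disjoint limits
  same <- gene_set_collection(list(S = c("g1", "g2")), "cell_signature")
  sameg <- gene_set_collection(list(S2 = c("g1", "g2")), "go_bp")
  expect_equal(jaccard_matrix(same, sameg)[1, 1], 1)
  disj <- gene_set_collection(list(D = c("zz1", "zz2")), "go_bp")
  expect_equal(jaccard_matrix(same, disj)[1, 1], 0)
})

test_that("median_overlap_expression takes midpoint medians, 0 on empty", {
  toy <- toy_fixture()
  M <- median_overlap_expression(toy$cells, toy$gos, toy$ev)
  expect_equal(M["A", "GO1"], 3)    # genes g1,g2 -> (2+4)/2
  expect_equal(M["C", "GO2"], 5)    # singleton overlap g5
  expect_equal(M["C", "GO1"], 0)    # empty overlap
  for (i in names(toy$cell_list)) for (j in names(toy$go_list)) {
    ov <- intersect(toy$cell_list[[i]], toy$go_list[[j]])
    exp_med <- if (length(ov)) stats::median(unname(toy$ev[ov])) else 0
    expect_equal(M[i, j], exp_med)
  }
  expect_error(
    median_overlap_expression(toy$cells, toy$gos, toy$ev[c("g1", "g2")]),
    "restrict_to_universe")
})

test_that("bipartite weights are the elementwise Jaccard x median product", {
  toy <- toy_fixture()
  J <- jaccard_matrix(toy$cells, toy$gos)
  M <- median_overlap_expression(toy$cells, toy$gos, toy$ev)
  bw <- bipartite_weights(J, M, sample_id = "s")
  expect_equal(bw$W["A", "GO1"], 2)         # (2/3) * 3
  expect_equal(bw$W, J * M)
  expect_equal(bw$W,
               bipartite_brute(toy$cell_list, toy$go_list, toy$ev))
  expect_true(all(bw$W[J == 0] == 0))       # annihilation
  expect_error(bipartite_weights(J, M[, 1, drop = FALSE]), "dimensions")
})

test_that("crosstalk projection equals the brute-force triple loop", {
  set.seed(7)
  for (rep in 1:5) {
    n_c <- sample(2:6, 1); n_g <- sample(1:8, 1)
    W <- matrix(stats::runif(n_c * n_g) * rbinom(n_c * n_g, 1, 0.6),
                n_c, n_g,
                dimnames = list(paste0("c", 1:n_c), paste0("t", 1:n_g)))
    bw <- structure(list(W = W, cells = rownames(W),
                         go_terms = colnames(W), sample_id = "s"),
                    class = "bipartite_weights")
    ct <- crosstalk_adjacency(bw)
    expect_equal(ct$R, crosstalk_brute(W), tolerance = 1e-9)
    expect_identical(ct$R, t(ct$R))                 # exact symmetry
    expect_true(all(diag(ct$R) == 0))
    expect_true(all(ct$R >= 0))
  }
})

test_that("two cells sharing one GO term get weight a*b; singles get zero", {
  W <- matrix(c(2, 3), nrow = 2,
              dimnames = list(c("x", "y"), "t1"))
  bw <- structure(list(W = W, cells = rownames(W), go_terms = "t1",
                       sample_id = "s"), class = "bipartite_weights")
  expect_equal(crosstalk_adjacency(bw)$R["x", "y"], 6)
  # disjoint GO neighborhoods -> zero crosstalk
  W2 <- matrix(c(1, 0, 0, 2), 2,
               dimnames = list(c("x", "y"), c("t1", "t2")))
  bw2 <- structure(list(W = W2, cells = rownames(W2),
                        go_terms = colnames(W2), sample_id = "s"),
                   class = "bipartite_weights")
  expect_true(all(crosstalk_adjacency(bw2)$R == 0))
  # single cell: 1x1 zero matrix
  W3 <- matrix(5, 1, 1, dimnames = list("x", "t1"))
  bw3 <- structure(list(W = W3, cells = "x", go_terms = "t1",
                        sample_id = "s"), class = "bipartite_weights")
  expect_identical(unname(crosstalk_adjacency(bw3)$R), matrix(0, 1, 1))
})

test_that("scaling expression by a power of two scales M by alpha, R by alpha^2", {
  toy <- toy_fixture()
  J <- jaccard_matrix(toy$cells, toy$gos)
  M1 <- median_overlap_expression(toy$cells, toy$gos, toy$ev)
  alpha <- 4                      # power of two: float-exact scaling
  M2 <- median_overlap_expression(toy$cells, toy$gos, alpha * toy$ev)
  expect_identical(M2, alpha * M1)
  R1 <- crosstalk_adjacency(bipartite_weights(J, M1))$R
  R2 <- crosstalk_adjacency(bipartite_weights(J, M2))$R
  expect_identical(R2, alpha^2 * R1)
  # non-dyadic factor: equal to tight tolerance
  M3 <- median_overlap_expression(toy$cells, toy$gos, 1.7 * toy$ev)
  R3 <- crosstalk_adjacency(bipartite_weights(J, M3))$R
  expect_equal(R3, 1.7^2 * R1, tolerance = 1e-12)
})

test_that("permuting cell order permutes rows/columns of R identically", {
  toy <- toy_fixture()
  perm <- c("C", "A", "B")
  ct1 <- crosstalk_adjacency(bipartite_weights(
    jaccard_matrix(toy$cells, toy$gos),
    median_overlap_expression(toy$cells, toy$gos, toy$ev)))
  cells_p <- toy$cells[match(perm, names(toy$cells))]
  ct2 <- crosstalk_adjacency(bipartite_weights(
    jaccard_matrix(cells_p, toy$gos),
    median_overlap_expression(cells_p, toy$gos, toy$ev)))
  expect_equal(ct2$R, ct1$R[perm, perm])
})

test_that("jaccard is sample-independent and reusable across a cohort", {
  toy <- toy_fixture()
  J1 <- jaccard_matrix(toy$cells, toy$gos)
  ev2 <- toy$ev * 3 + 1
  J2 <- jaccard_matrix(toy$cells, toy$gos)  # recomputed "per sample"
  expect_identical(J1, J2)
})

test_that("edge-list export writes positive upper-triangle edges", {
  toy <- toy_fixture()
  ct <- crosstalk_adjacency(bipartite_weights(
    jaccard_matrix(toy$cells, toy$gos),
    median_overlap_expression(toy$cells, toy$gos, toy$ev)))
  path <- tempfile(fileext = ".tsv")
  write_edge_list(ct, path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_true(all(df$weight > 0))
  for (r in seq_len(nrow(df)))
    expect_equal(df$weight[r], ct$R[df$cell_i[r], df$cell_j[r]])
})
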