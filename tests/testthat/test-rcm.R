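test_that("adjacency construction follows the pattern, not the values", {
  ## worked-example square pattern, symmetrised, diagonal dropped:
  ## edges {1-3} and {2-3} only
  G <- build_adjacency(worked_example())
  expect_identical(G$mode, "symmetric")
  expect_identical(G$adj, list(3L, 3L, c(1L, 2L)))
  expect_identical(node_degrees(G), c(1L, 1L, 2L))

  ## a diagonal matrix has no off-diagonal links
  D <- build_adjacency(mutation_matrix(diag(3)))
  expect_identical(node_degrees(D), c(0L, 0L, 0L))

  ## fully dense 2x3 gives the complete bipartite graph K_{2,3}
  K <- build_adjacency(mutation_matrix(matrix(1, 2, 3)))
  expect_identical(K$mode, "bipartite")
  expect_identical(node_degrees(K), c(3L, 3L, 2L, 2L, 2L))
  expect_identical(sum(lengths(K$adj)) / 2, 6)

  ## path graph degrees
  P <- build_adjacency(gen_banded(3, band_width = 1))
  expect_identical(node_degrees(P), c(1L, 2L, 1L))

  expect_error(build_adjacency(mutation_matrix(matrix(1, 2, 3)),
                               mode = "symmetric"), "square")
})

test_that("Cuthill-McKee traversal follows the printed tie rules", {
  ## path 1-2-3-4: endpoint has minimum degree, lowest index starts
  P4 <- build_adjacency(gen_banded(4, band_width = 1))
  expect_identical(cuthill_mckee(P4), 1:4)

  ## single node
  one <- build_adjacency(mutation_matrix(matrix(1, 1, 1), "S1", "G1"),
                         mode = "symmetric")
  expect_identical(cuthill_mckee(one), 1L)

  ## two disconnected edges restart at the next minimum-degree node
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  G <- build_adjacency(mutation_matrix(A))
  expect_identical(cuthill_mckee(G), 1:4)

  ## orderings are always permutations (random graphs)
  for (seed in 1:10) {
    M <- random_mm(seed)
    G <- build_adjacency(M, mode = "bipartite")
    R <- cuthill_mckee(G)
    expect_identical(sort(R), seq_len(G$n_nodes))
  }
})

test_that("reversal is an involution and preserves bandwidth", {
  expect_identical(reverse_ordering(1:4), 4:1)
  expect_identical(reverse_ordering(c(3L, 1L, 2L)), c(2L, 1L, 3L))
  R <- sample(10)
  expect_identical(reverse_ordering(reverse_ordering(R)), R)

  ## bandwidth of a symmetric pattern is unchanged by reversing an ordering
  for (seed in 1:5) {
    set.seed(seed)
    n <- 15
    A <- matrix(0, n, n)
    A[sample(n * n, 30)] <- 1
    A <- pmax(A, t(A))
    M <- mutation_matrix(A)
    ord <- cuthill_mckee(build_adjacency(M))
    expect_identical(ordered_bandwidth(M, ord),
                     ordered_bandwidth(M, rev(ord)))
  }
})

test_that("bandwidth measures the widest diagonal distance", {
  expect_identical(bandwidth(mutation_matrix(diag(4))), 0L)
  expect_identical(bandwidth(worked_example()), 2L)
  expect_identical(bandwidth(gen_banded(6, band_width = 1)), 1L)
  expect_identical(bandwidth(mutation_matrix(matrix(0, 3, 3))), 0L)
  ## rectangular patterns are measured on the bipartite expansion
  B <- mutation_matrix(matrix(c(1, 0, 0, 0, 0, 0), 2, 3))
  expect_identical(bandwidth(B), 2L)   # cell (1,1) sits at (1, m+1)
})

test_that("reordering renumbers banded structure back to its band", {
  ## already-banded input stays optimal
  T5 <- gen_banded(5, band_width = 1)
  pp <- rcm_permutations(T5)
  expect_identical(bandwidth(apply_permutations(T5, pp)), 1L)

  ## shuffled tridiagonal is provably restored to bandwidth 1
  T12 <- gen_banded(12, band_width = 1)
  sh <- shuffle_axes(T12, seed = 99, symmetric = TRUE)
  expect_gte(bandwidth(sh$matrix), 1L)
  pp <- rcm_permutations(sh$matrix)
  expect_identical(bandwidth(apply_permutations(sh$matrix, pp)), 1L)

  ## applying a permutation pair then its inverse restores the matrix
  for (seed in 1:5) {
    M <- random_mm(seed)
    pp <- rcm_permutations(M)
    expect_same_cells(apply_permutations(apply_permutations(M, pp),
                                         invert_permutations(pp)), M)
  }
})

test_that("permutation splitting respects the bipartite node roles", {
  M <- random_mm(17)
  G <- build_adjacency(M, mode = "bipartite")
  Rv <- reverse_ordering(cuthill_mckee(G))
  pp <- rcm_permutations(M, mode = "bipartite")
  m <- nrow(M)
  expect_identical(pp$row_perm[Rv[Rv <= m]], seq_len(m))
  expect_identical(pp$col_perm[Rv[Rv > m] - m], seq_len(ncol(M)))
  expect_identical(sort(pp$row_perm), seq_len(nrow(M)))
  expect_identical(sort(pp$col_perm), seq_len(ncol(M)))
})

test_that("the compiled pipeline reproduces the reference ordering exactly", {
  for (seed in 1:12) {
    M <- random_mm(seed, m = sample(3:35, 1), n = sample(4:45, 1))
    pp <- rcm_permutations(M, mode = "bipartite")
    tr <- casagm:::dense_triplets(M)
    it0 <- (tr$i - 1L) * ncol(M) + (tr$j - 1L)
    res <- casagm:::casagm_reorder_csr(it0, tr$v, nrow(M), ncol(M))
    expect_identical(res$row_perm, pp$row_perm)
    expect_identical(res$col_perm, pp$col_perm)
  }
})
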