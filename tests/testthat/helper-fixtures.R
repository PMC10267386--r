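## The 3x3 worked-example matrix: non-zeros at (1,1),(1,3),(2,3),(3,1),
## (3,2),(3,3) with positional stand-in values 1..6 in row-major order.
worked_example <- function() {
  mutation_matrix(matrix(c(1, 0, 2,
                           0, 0, 3,
                           4, 5, 6), 3, 3, byrow = TRUE))
}

## a seeded random mutation matrix for property sweeps
random_mm <- function(seed, m = NULL, n = NULL, sparsity = NULL,
                      model = NULL) {
  set.seed(seed)
  if (is.null(m)) m <- sample(2:40, 1)
  if (is.null(n)) n <- sample(2:50, 1)
  if (is.null(sparsity)) sparsity <- runif(1, 0.5, 50)
  if (is.null(model)) model <- sample(c("snv_counts", "cnv_signed"), 1)
  generate_matrix(m, n, sparsity_pct = sparsity, value_model = model,
                  seed = seed)
}

expect_same_cells <- function(a, b) {
  expect_identical(unname(as.matrix(a)), unname(as.matrix(b)))
}

## independent reverse Cuthill-McKee reference (scipy.sparse.csgraph),
## returning the 1-based new->old ordering for a square symmetric pattern
scipy_rcm_order <- function(M) {
  f <- tempfile(fileext = ".mtx")
  on.exit(unlink(f))
  write_matrix_market(M, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import sys, scipy.io\n",
    "from scipy.sparse.csgraph import reverse_cuthill_mckee\n",
    "A = scipy.io.mmread(sys.argv[1]).tocsr()\n",
    "p = reverse_cuthill_mckee(A, symmetric_mode=True)\n",
    "print(' '.join(map(str, p)))")), f), stdout = TRUE)
  as.integer(strsplit(out[length(out)], " ", fixed = TRUE)[[1]]) + 1L
}

## bandwidth after applying a square new->old ordering
ordered_bandwidth <- function(M, ord) {
  bandwidth(mutation_matrix(as.matrix(M)[ord, ord, drop = FALSE]))
}
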