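#' Characterise a dataset the way the benchmark tables do
#'
#' Computes the per-dataset statistics used to relate compression behaviour
#' to the input: total cell count, non-zero count, sparsity (percentage of
#' non-zero cells), row count, rows/columns percentage, source file size,
#' matrix norms and numerical rank.
#'
#' Norm and rank conventions are the MATLAB defaults for a dense matrix:
#' L1 is the operator 1-norm (maximum absolute column sum), L2 the spectral
#' norm (largest singular value), and the rank counts singular values above
#' `max(m, n) * eps * sigma_max`.
#'
#' @param M a [mutation_matrix()].
#' @param file_size_bytes size of the source file in bytes (`NA` if the
#'   matrix did not come from a file).
#' @param nonneg_ratio also report the percentage of non-zero entries that
#'   are non-negative (meaningful for signed CNV-style data).
#' @param norms compute the SVD-based statistics (`l2_norm`, `rank`).  Can
#'   be disabled for speed when only the counting columns are needed.
#' @return a one-row `data.frame` of class `dataset_profile`.
#' @examples
#' profile_dataset(mutation_matrix(diag(4)))
#' @export
profile_dataset <- function(M, file_size_bytes = NA_real_,
                            nonneg_ratio = FALSE, norms = TRUE) {
  stopifnot(is_mutation_matrix(M))
  A <- as.matrix(M)
  m <- nrow(A)
  n <- ncol(A)
  k <- sum(A != 0)
  l1 <- if (k) max(colSums(abs(A))) else 0
  l2 <- NA_real_
  rk <- NA_integer_
  if (norms) {
    if (k == 0L) {
      l2 <- 0
      rk <- 0L
    } else {
      d <- svd(A, nu = 0L, nv = 0L)$d
      l2 <- d[1L]
      rk <- sum(d > max(m, n) * .Machine$double.eps * d[1L])
    }
  }
  nn <- if (nonneg_ratio) {
    if (k == 0L) NA_real_ else 100 * sum(A > 0) / k
  } else {
    NA_real_
  }
  out <- data.frame(
    dataset_size = m * n,
    nnz = k,
    sparsity_pct = 100 * k / (m * n),
    rows = m,
    cols = n,
    rows_over_cols_pct = 100 * m / n,
    file_size_bytes = file_size_bytes,
    l1_norm = l1,
    l2_norm = l2,
    rank = rk,
    nonneg_ratio_pct = nn
  )
  class(out) <- c("dataset_profile", class(out))
  out
}
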