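## Seeded generators for mutation-like matrices.
##
## The generators control the storage-relevant structure exactly: the
## non-zero count is hit exactly (cells drawn without replacement, so the
## sparsity covariate of the correlation analyses is not itself noisy),
## SNV-like values are small positive integers (mutation counts), CNV-like
## values are signed integers (copy-number gain/loss) with an exact split
## of positive entries.  All randomness goes through one fixed RNG
## (Mersenne-Twister / Inversion / Rejection), so one argument set plus a
## seed yields the same matrix on every platform.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) {
    assign(".Random.seed", old, globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

#' Generate a synthetic mutation-like matrix
#'
#' Draws exactly `round(sparsity_pct * m * n / 100)` non-zero cells without
#' replacement and fills them under the chosen value model:
#' `"snv_counts"` gives small positive integers in 1..9, `"cnv_signed"`
#' gives signed integers with magnitudes 1..4 and exactly
#' `round(nonneg_ratio_pct * nnz / 100)` positive entries.
#'
#' `structure` controls placement: `"uniform"` scatters cells anywhere;
#' `"banded"` restricts them to the scaled diagonal band
#' `|i - j * m / n| <= band_width`; `"clustered"` confines them to
#' `clusters` randomly placed blocks.
#'
#' @param m,n dimensions.
#' @param sparsity_pct target percentage of non-zero cells in (0, 100].
#' @param value_model `"snv_counts"` or `"cnv_signed"`.
#' @param nonneg_ratio_pct for `"cnv_signed"`: percentage of non-zeros that
#'   are positive.
#' @param structure `"uniform"`, `"banded"` or `"clustered"`.
#' @param band_width half-width of the band for `structure = "banded"`.
#' @param clusters number of blocks for `structure = "clustered"`.
#' @param seed RNG seed; identical arguments and seed give an identical
#'   matrix.
#' @return a [mutation_matrix()].
#' @examples
#' M <- generate_matrix(50, 80, sparsity_pct = 2, seed = 1)
#' nnz(M)  # exactly round(0.02 * 50 * 80)
#' @export
generate_matrix <- function(m, n, sparsity_pct,
                            value_model = c("snv_counts", "cnv_signed"),
                            nonneg_ratio_pct = 50,
                            structure = c("uniform", "banded", "clustered"),
                            band_width = max(1L, round(min(m, n) / 10)),
                            clusters = 4L, seed = NULL) {
  value_model <- match.arg(value_model)
  structure <- match.arg(structure)
  stopifnot(m >= 1L, n >= 1L, sparsity_pct > 0, sparsity_pct <= 100,
            nonneg_ratio_pct >= 0, nonneg_ratio_pct <= 100)
  k <- round(sparsity_pct * m * n / 100)
  if (k > m * n) stop("requested non-zero count exceeds the matrix size",
                      call. = FALSE)
  with_seed(seed, {
    eligible <- switch(structure,
      uniform = NULL,
      banded = banded_cells(m, n, band_width),
      clustered = clustered_cells(m, n, clusters, k))
    pos <- if (is.null(eligible)) {
      sample.int(m * n, k)
    } else {
      if (length(eligible) < k) {
        stop("structure admits fewer cells than the requested non-zero ",
             "count", call. = FALSE)
      }
      eligible[sample.int(length(eligible), k)]
    }
    v <- switch(value_model,
      snv_counts = sample(1:9, k, replace = TRUE),
      cnv_signed = {
        npos <- round(nonneg_ratio_pct * k / 100)
        sgn <- sample(c(rep(1L, npos), rep(-1L, k - npos)))
        sgn * sample(1:4, k, replace = TRUE)
      })
    A <- matrix(0, m, n)
    A[pos] <- v
    mutation_matrix(A)
  })
}

## linear indices (column-major) of the scaled diagonal band
banded_cells <- function(m, n, bw) {
  j <- seq_len(n)
  centre <- (j - 1) * m / n
  lo <- pmax(1L, ceiling(centre - bw) + 1L)
  hi <- pmin(m, floor(centre + bw) + 1L)
  keep <- lo <= hi
  unlist(lapply(which(keep), function(jj) {
    (jj - 1L) * m + (lo[jj]:hi[jj])
  }), use.names = FALSE)
}

clustered_cells <- function(m, n, clusters, k) {
  ## square-ish blocks sized so their union holds ~2k cells
  side <- max(2L, ceiling(sqrt(2 * k / clusters)))
  br <- min(side, m)
  bc <- min(ceiling(2 * k / (clusters * br)), n)
  cells <- lapply(seq_len(clusters), function(q) {
    r0 <- sample.int(m - br + 1L, 1L) - 1L
    c0 <- sample.int(n - bc + 1L, 1L) - 1L
    rows <- r0 + seq_len(br)
    cols <- c0 + seq_len(bc)
    as.vector(outer(rows, (cols - 1L) * m, `+`))
  })
  unique(unlist(cells, use.names = FALSE))
}

#' Deterministic banded matrix
#'
#' Fills every cell of the scaled diagonal band `|i - j * m / n| <=
#' band_width` with `value` -- e.g. `gen_banded(12, band_width = 1)` is the
#' 12 x 12 tridiagonal pattern used to exercise bandwidth recovery.
#'
#' @param m,n dimensions (default square).
#' @param band_width half-width of the band.
#' @param value the non-zero value.
#' @return a [mutation_matrix()].
#' @export
gen_banded <- function(m, n = m, band_width = 1L, value = 1) {
  A <- matrix(0, m, n)
  A[banded_cells(m, n, band_width)] <- value
  mutation_matrix(A)
}

#' Randomly permute the axes of a matrix
#'
#' Scatters a matrix's non-zeros by renumbering rows and columns with
#' seeded random permutations -- the condition a bandwidth-reducing
#' reordering is meant to undo.  Returns the permutations so tests can
#' verify recovery.  With `symmetric = TRUE` (square input) one permutation
#' is applied to both axes, which preserves pattern symmetry.
#'
#' @param M a [mutation_matrix()].
#' @param seed RNG seed.
#' @param symmetric use the same permutation for rows and columns.
#' @return list with elements `matrix` (the shuffled [mutation_matrix()])
#'   and `perm` (the `permutation_pair` applied, old-to-new).
#' @export
shuffle_axes <- function(M, seed = NULL, symmetric = FALSE) {
  stopifnot(is_mutation_matrix(M))
  m <- nrow(M)
  n <- ncol(M)
  if (symmetric && m != n) {
    stop("symmetric shuffling requires a square matrix", call. = FALSE)
  }
  with_seed(seed, {
    rp <- sample.int(m)
    cp <- if (symmetric) rp else sample.int(n)
    pp <- structure(list(row_perm = rp, col_perm = cp),
                    class = "permutation_pair")
    list(matrix = apply_permutations(M, pp), perm = pp)
  })
}

#' Reference dataset characteristics for the SNV and CNV regimes
#'
#' Published per-dataset characteristics of the nine TCGA level-3 SNV
#' cohorts and six CNV cohorts that define the benchmark regimes emulated
#' by [generate_regime_suite()]: total cell count, non-zero count, the
#' percentages derived from them, source file size and matrix norms.
#'
#' @return a data.frame, one row per cohort.
#' @export
snv_regimes <- function() {
  read.delim(system.file("extdata", "snv_regimes.tsv", package = "casagm"),
             check.names = FALSE)
}

#' @rdname snv_regimes
#' @export
cnv_regimes <- function() {
  read.delim(system.file("extdata", "cnv_regimes.tsv", package = "casagm"),
             check.names = FALSE)
}

#' Generate the full synthetic benchmark suite for one regime
#'
#' One matrix per cohort of [snv_regimes()] / [cnv_regimes()], with the
#' cohort's row count, column count (`dataset_size / rows`, integral for
#' every cohort) and exact non-zero count; CNV matrices also reproduce the
#' cohort's non-negative ratio.  Sub-seeds are derived from `seed`, so the
#' whole suite is reproducible from one integer.
#'
#' @param kind `"snv"` or `"cnv"`.
#' @param seed RNG seed for the suite.
#' @return a named list of [mutation_matrix()] objects.
#' @export
generate_regime_suite <- function(kind = c("snv", "cnv"), seed = 1L) {
  kind <- match.arg(kind)
  tab <- if (kind == "snv") snv_regimes() else cnv_regimes()
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, nrow(tab)))
  out <- lapply(seq_len(nrow(tab)), function(q) {
    m <- tab$rows[q]
    n <- as.integer(round(tab$dataset_size[q] / m))
    generate_matrix(
      m, n,
      sparsity_pct = 100 * tab$nnz[q] / (as.double(m) * n),
      value_model = if (kind == "snv") "snv_counts" else "cnv_signed",
      nonneg_ratio_pct = if (kind == "cnv") tab$nonneg_ratio_pct[q] else 50,
      seed = sub_seeds[q])
  })
  names(out) <- tab$dataset
  out
}
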