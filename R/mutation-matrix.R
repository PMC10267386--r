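#' casagm: structural lossless compression for sparse mutation matrices
#'
#' Sample-by-gene mutation matrices from SNV and CNV profiling are extremely
#' sparse and markedly rectangular (a few hundred samples against ~12,000
#' genes).  This package stores them losslessly in the three classic sparse
#' encodings -- coordinate triplets (COO), compressed sparse column (CSC) and
#' compressed sparse row (CSR) -- and adds a reordering pipeline that presorts
#' the non-zeros row-major, renumbers rows and columns with the reverse
#' Cuthill-McKee algorithm so scattered non-zeros converge towards the
#' diagonal, and serialises the result as CSR plus the permutations needed to
#' undo the renumbering exactly.
#'
#' Entry points: [mutation_matrix()] and the readers [read_dense_tsv()] /
#' [read_matrix_market()]; [compress()] / [decompress()] with
#' [write_casg()] / [read_casg()]; [run_benchmark()] for the evaluation
#' metrics; [generate_matrix()] and [generate_regime_suite()] for synthetic
#' inputs.
#'
#' @useDynLib casagm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median pt sd
#' @importFrom utils read.delim
#' @keywords internal
"_PACKAGE"

#' Construct a labelled mutation matrix
#'
#' A `mutation_matrix` is a dense numeric matrix of mutation values (samples
#' in rows, genes in columns) carrying unique row and column labels.  It is
#' the uncompressed object all codecs operate on.
#'
#' @param values numeric matrix (or object coercible to one); all cells must
#'   be finite.
#' @param row_labels,col_labels character vectors of unique axis labels.
#'   Default to existing dimnames, else `S1..Sm` / `G1..Gn`.
#' @return a `mutation_matrix`: a base matrix with class attribute and
#'   dimnames set.
#' @examples
#' M <- mutation_matrix(matrix(c(1, 0, 4, 0, 0, 5, 2, 3, 6), 3, 3, byrow = TRUE))
#' nnz(M)
#' @export
mutation_matrix <- function(values, row_labels = NULL, col_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("mutation matrix values must be numeric", call. = FALSE)
  }
  storage.mode(values) <- "double"
  m <- nrow(values)
  n <- ncol(values)
  if (m < 1L || n < 1L) {
    stop("mutation matrix must have at least one row and one column",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("mutation matrix cells must all be finite", call. = FALSE)
  }
  if (is.null(row_labels)) row_labels <- rownames(values)
  if (is.null(col_labels)) col_labels <- colnames(values)
  if (is.null(row_labels)) row_labels <- paste0("S", seq_len(m))
  if (is.null(col_labels)) col_labels <- paste0("G", seq_len(n))
  row_labels <- as.character(row_labels)
  col_labels <- as.character(col_labels)
  if (length(row_labels) != m || anyDuplicated(row_labels)) {
    stop("row labels must be unique and match the row count", call. = FALSE)
  }
  if (length(col_labels) != n || anyDuplicated(col_labels)) {
    stop("column labels must be unique and match the column count",
         call. = FALSE)
  }
  dimnames(values) <- list(row_labels, col_labels)
  class(values) <- c("mutation_matrix", class(values))
  values
}

#' @rdname mutation_matrix
#' @param x object to test or coerce.
#' @export
is_mutation_matrix <- function(x) inherits(x, "mutation_matrix")

#' @export
as.matrix.mutation_matrix <- function(x, ...) {
  class(x) <- setdiff(class(x), "mutation_matrix")
  x
}

#' Number of structural non-zeros
#'
#' @param x a `mutation_matrix` (or plain matrix).
#' @return integer count of cells different from zero.
#' @export
nnz <- function(x) sum(x != 0)

#' Percentage of non-zero cells
#'
#' Sparsity here follows the convention of the mutation-storage literature:
#' `100 * nnz / (m * n)`, so a *higher* value means a *denser* matrix.
#'
#' @param x a `mutation_matrix` (or plain matrix).
#' @return percentage in `[0, 100]`.
#' @export
sparsity_pct <- function(x) 100 * nnz(x) / (nrow(x) * ncol(x))

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d samples x %d genes, nnz = %d (%.3f%%)\n",
              nrow(x), ncol(x), nnz(x), sparsity_pct(x)))
  mm <- as.matrix(x)
  if (nrow(mm) <= 10L && ncol(mm) <= 10L) {
    print(mm)
  } else {
    cat("first cells:\n")
    print(mm[seq_len(min(4L, nrow(mm))), seq_len(min(6L, ncol(mm))), drop = FALSE])
  }
  invisible(x)
}

## Internal fast constructor: values already validated (decoded from a
## checked container or produced by a generator), so the finiteness and
## label scans of mutation_matrix() are skipped.  `labels = NULL` leaves
## dimnames unset.
new_mm <- function(values, labels = NULL) {
  dimnames(values) <- labels
  class(values) <- c("mutation_matrix", class(values))
  values
}

## Internal: extract non-zero triplets in row-major order without building a
## codec object.  Returns 1-based i/j.  Scans the transpose so the row-major
## enumeration falls out of R's column-major storage directly.
dense_triplets <- function(M) {
  m <- nrow(M)
  n <- ncol(M)
  tM <- t.default(M)   # single pass; no class-stripping copy first
  it <- which(tM != 0)
  if (length(it) == 0L) {
    return(list(i = integer(0), j = integer(0), v = double(0), m = m, n = n))
  }
  it0 <- it - 1L
  list(i = it0 %/% n + 1L, j = it0 %% n + 1L, v = tM[it], m = m, n = n)
}
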