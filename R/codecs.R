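## Sparse codec objects.
##
## Index arrays follow the storage-format convention and are 0-based (as in
## the on-disk encodings and in compressed-column objects elsewhere); dense
## matrices stay 1-based R matrices.  Encoders drop explicit zeros; decoders
## reject duplicate or out-of-range coordinates rather than summing them,
## because a mutation matrix has exactly one cell per (sample, gene) and a
## duplicate can only mean corrupt input.

new_coo <- function(i, j, v, m, n, labels = NULL) {
  structure(list(i = as.integer(i), j = as.integer(j), v = as.double(v),
                 m = as.integer(m), n = as.integer(n), labels = labels),
            class = "coo_matrix")
}

new_csc <- function(indptr, indices, values, m, n, labels = NULL) {
  structure(list(indptr = as.integer(indptr), indices = as.integer(indices),
                 values = as.double(values), m = as.integer(m),
                 n = as.integer(n), labels = labels),
            class = "csc_matrix")
}

new_csr <- function(indptr, indices, values, m, n, labels = NULL) {
  structure(list(indptr = as.integer(indptr), indices = as.integer(indices),
                 values = as.double(values), m = as.integer(m),
                 n = as.integer(n), labels = labels),
            class = "csr_matrix")
}

#' @export
print.coo_matrix <- function(x, ...) {
  cat(sprintf("COO triplets: %d x %d, nnz = %d\n", x$m, x$n, length(x$v)))
  invisible(x)
}

#' @export
print.csc_matrix <- function(x, ...) {
  cat(sprintf("CSC form: %d x %d, nnz = %d\n", x$m, x$n, length(x$values)))
  invisible(x)
}

#' @export
print.csr_matrix <- function(x, ...) {
  cat(sprintf("CSR form: %d x %d, nnz = %d\n", x$m, x$n, length(x$values)))
  invisible(x)
}

keep_labels <- function(M) dimnames(M)

#' Encode a matrix as coordinate (COO) triplets
#'
#' Enumerates the non-zero cells in canonical row-major order (row
#' ascending, then column ascending) into three parallel arrays: 0-based row
#' indices `i`, 0-based column indices `j` and values `v`.
#'
#' @param M a [mutation_matrix()] (or plain numeric matrix).
#' @return a `coo_matrix` object.
#' @examples
#' A <- mutation_matrix(matrix(c(1, 0, 2, 0, 0, 3, 4, 5, 6), 3, 3, byrow = TRUE))
#' coo_encode(A)$i    # 0 0 1 2 2 2
#' @export
coo_encode <- function(M) {
  tr <- dense_triplets(M)
  new_coo(tr$i - 1L, tr$j - 1L, tr$v, tr$m, tr$n, labels = keep_labels(M))
}

#' Decode COO triplets back to the dense matrix
#'
#' Places `v[k]` at position `(i[k], j[k])` and zeros elsewhere.  This is the
#' textbook triplet decode: one placement per stored non-zero.
#'
#' @param T a `coo_matrix` from [coo_encode()].
#' @return a [mutation_matrix()].
#' @export
coo_decode <- function(T) {
  stopifnot(inherits(T, "coo_matrix"))
  m <- T$m
  n <- T$n
  i <- T$i
  j <- T$j
  v <- T$v
  if (length(i) != length(j) || length(j) != length(v)) {
    stop("triplet arrays have unequal lengths", call. = FALSE)
  }
  if (length(i) && (min(i) < 0L || max(i) >= m || min(j) < 0L || max(j) >= n)) {
    stop("triplet index out of bounds", call. = FALSE)
  }
  if (anyDuplicated(i * as.double(n) + j)) {
    stop("duplicate coordinate in triplet set", call. = FALSE)
  }
  A <- matrix(0, m, n)
  i1 <- i + 1L
  j1 <- j + 1L
  for (k in seq_along(v)) A[i1[k], j1[k]] <- v[k]
  finish_decode(A, T$labels)
}

finish_decode <- function(A, labels) {
  new_mm(A, labels)
}

#' Encode a matrix in compressed sparse column (CSC) form
#'
#' Walks the matrix column by column; for column `i` the 0-based row indices
#' of its non-zeros land in `indices[(indptr[i] + 1):indptr[i + 1]]` (R
#' slice of the 0-based half-open range `indptr[i]:indptr[i+1]`) with the
#' values alongside.
#'
#' @param M a [mutation_matrix()] (or plain numeric matrix).
#' @return a `csc_matrix` object.
#' @examples
#' A <- mutation_matrix(matrix(c(1, 0, 2, 0, 0, 3, 4, 5, 6), 3, 3, byrow = TRUE))
#' csc_encode(A)$indptr    # 0 2 3 6
#' @export
csc_encode <- function(M) {
  m <- nrow(M)
  n <- ncol(M)
  indptr <- integer(n + 1L)
  il <- vector("list", n)
  vl <- vector("list", n)
  for (jj in seq_len(n)) {
    col <- M[, jj]
    nz <- which(col != 0)
    indptr[jj + 1L] <- indptr[jj] + length(nz)
    il[[jj]] <- nz
    vl[[jj]] <- col[nz]
  }
  new_csc(indptr, unlist(il, use.names = FALSE) - 1L,
          unlist(vl, use.names = FALSE), m, n, labels = keep_labels(M))
}

check_compressed <- function(indptr, indices, axis_len, extent, what) {
  if (length(indptr) != axis_len + 1L || indptr[1L] != 0L) {
    stop(what, " pointer array malformed", call. = FALSE)
  }
  if (is.unsorted(indptr)) {
    stop(what, " pointer array must be non-decreasing", call. = FALSE)
  }
  if (indptr[axis_len + 1L] != length(indices)) {
    stop(what, " pointer array does not match the index array length",
         call. = FALSE)
  }
  if (length(indices) && (min(indices) < 0L || max(indices) >= extent)) {
    stop(what, " index out of bounds", call. = FALSE)
  }
  invisible(TRUE)
}

#' Decode a CSC form back to the dense matrix
#'
#' @param C a `csc_matrix` from [csc_encode()].
#' @return a [mutation_matrix()].
#' @export
csc_decode <- function(C) {
  stopifnot(inherits(C, "csc_matrix"))
  m <- C$m
  n <- C$n
  check_compressed(C$indptr, C$indices, n, m, "CSC")
  A <- matrix(0, m, n)
  ip <- C$indptr
  ind <- C$indices
  val <- C$values
  off <- 1L
  for (jj in seq_len(n)) {
    lo <- ip[jj]
    hi <- ip[jj + 1L]
    if (hi == lo + 1L) {           # singleton column: skip slice building
      A[ind[hi] + off] <- val[hi]
    } else if (hi > lo) {
      s <- (lo + 1L):hi
      A[ind[s] + off] <- val[s]
    }
    off <- off + m
  }
  finish_decode(A, C$labels)
}

#' Encode a matrix in compressed sparse row (CSR) form
#'
#' Row-major mirror of [csc_encode()]: one pointer per row delimits its
#' non-zeros in the shared 0-based column-index and value arrays.
#' `csr_encode(M)` carries the same index arrays as `csc_encode(t(M))` with
#' the axes relabelled.
#'
#' @param M a [mutation_matrix()] (or plain numeric matrix).
#' @return a `csr_matrix` object.
#' @export
csr_encode <- function(M) {
  m <- nrow(M)
  n <- ncol(M)
  indptr <- integer(m + 1L)
  il <- vector("list", m)
  vl <- vector("list", m)
  for (ii in seq_len(m)) {
    row <- M[ii, ]
    nz <- which(row != 0)
    indptr[ii + 1L] <- indptr[ii] + length(nz)
    il[[ii]] <- nz
    vl[[ii]] <- row[nz]
  }
  new_csr(indptr, unlist(il, use.names = FALSE) - 1L,
          unlist(vl, use.names = FALSE), m, n, labels = keep_labels(M))
}

#' Decode a CSR form back to the dense matrix
#'
#' @param C a `csr_matrix` from [csr_encode()].
#' @return a [mutation_matrix()].
#' @export
csr_decode <- function(C) {
  stopifnot(inherits(C, "csr_matrix"))
  m <- C$m
  n <- C$n
  check_compressed(C$indptr, C$indices, m, n, "CSR")
  A <- matrix(0, m, n)
  ip <- C$indptr
  ind <- C$indices
  val <- C$values
  for (ii in seq_len(m)) {
    lo <- ip[ii]
    hi <- ip[ii + 1L]
    if (hi == lo + 1L) {           # singleton row: skip slice building
      A[ind[hi] * m + ii] <- val[hi]
    } else if (hi > lo) {
      s <- (lo + 1L):hi
      A[ind[s] * m + ii] <- val[s]
    }
  }
  finish_decode(A, C$labels)
}

#' Stably sort a triplet set into row-major order
#'
#' First stage of the reordering pipeline: non-zeros are arranged by (row,
#' column) so that entries adjacent in the matrix are adjacent in storage.
#' Idempotent; the output is a permutation of the input triplets.
#'
#' @param T a `coo_matrix`.
#' @return the same triplets in row-major order.
#' @export
row_major_presort <- function(T) {
  stopifnot(inherits(T, "coo_matrix"))
  o <- order(T$i, T$j, method = "radix")
  new_coo(T$i[o], T$j[o], T$v[o], T$m, T$n, labels = T$labels)
}
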