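## The compression pipeline and its in-memory container.
##
## A `casg_container` is the stored form of one encoding: codec tag,
## dimensions, value type, the codec's index/value arrays, the row/column
## permutations when the reordering pipeline produced them, and (optionally)
## the axis labels.  `write_casg()`/`read_casg()` map it to the on-disk
## format byte for byte.

CODEC_LEVELS <- c("coo", "csc", "casagm")

#' Compress a mutation matrix
#'
#' `codec = "coo"` and `"csc"` encode the matrix directly.  `codec =
#' "casagm"` runs the reordering pipeline: non-zeros presorted row-major,
#' rows and columns renumbered by reverse Cuthill-McKee ([rcm_permutations()];
#' the symmetrised pattern for square input, the bipartite graph otherwise),
#' then CSR encoding on the renumbered axes.  The permutations are kept in
#' the container so decompression is exact -- without them the renumbering
#' would lose the original sample and gene order.
#'
#' For rectangular input the pipeline runs in a compiled kernel that is
#' order-identical to the R reference functions.
#'
#' @param M a [mutation_matrix()].
#' @param codec `"coo"`, `"csc"` or `"casagm"`.
#' @param store_labels keep row/column labels in the container (disable for
#'   matrix-only benchmarking).
#' @return a `casg_container`.
#' @examples
#' M <- mutation_matrix(matrix(c(1, 0, 2, 0, 0, 3, 4, 5, 6), 3, 3, byrow = TRUE))
#' decompress(compress(M, "casagm"))
#' @export
compress <- function(M, codec = c("coo", "csc", "casagm"),
                     store_labels = TRUE) {
  codec <- match.arg(codec)
  stopifnot(is_mutation_matrix(M))
  m <- nrow(M)
  n <- ncol(M)
  labels <- if (store_labels) dimnames(M) else NULL
  if (codec == "coo") {
    T <- coo_encode(M)
    payload <- list(i = T$i, j = T$j, values = T$v)
    k <- length(T$v)
    perms <- NULL
  } else if (codec == "csc") {
    C <- csc_encode(M)
    payload <- list(indptr = C$indptr, indices = C$indices,
                    values = C$values)
    k <- length(C$values)
    perms <- NULL
  } else {
    ## row-major scan of the dense matrix: the presorted non-zero stream
    tM <- t.default(M)
    it <- which(tM != 0)
    k <- length(it)
    if (k == 0L) {
      ## nothing to reorder: identity permutations, empty CSR
      payload <- list(indptr = integer(m + 1L), indices = integer(0),
                      values = double(0))
      perms <- list(row_perm = seq_len(m), col_perm = seq_len(n))
    } else if (m == n) {
      it0 <- it - 1L
      T <- row_major_presort(new_coo(it0 %/% n, it0 %% n, tM[it], m, n))
      pp <- rcm_permutations(M)
      ni <- pp$row_perm[T$i + 1L]
      nj <- pp$col_perm[T$j + 1L]
      o <- order(ni, nj, method = "radix")
      payload <- list(indptr = c(0L, cumsum(tabulate(ni, m))),
                      indices = nj[o] - 1L, values = T$v[o])
      perms <- list(row_perm = pp$row_perm, col_perm = pp$col_perm)
    } else {
      res <- casagm_reorder_csr(it - 1L, tM[it], m, n)
      payload <- list(indptr = res$indptr, indices = res$indices,
                      values = res$values)
      perms <- list(row_perm = res$row_perm, col_perm = res$col_perm)
    }
  }
  new_container(codec, m, n, k, payload, perms, labels)
}

new_container <- function(codec, m, n, nnz, payload, perms, labels) {
  structure(list(codec = codec, m = as.integer(m), n = as.integer(n),
                 nnz = as.integer(nnz),
                 value_type = detect_value_type(payload$values),
                 index_width = index_width(m, n, nnz),
                 payload = payload, perms = perms, labels = labels),
            class = "casg_container")
}

detect_value_type <- function(v) {
  if (length(v) == 0L) return("int8")
  if (all(v == trunc(v))) {
    r <- range(v)
    if (r[1L] >= -128 && r[2L] <= 127) return("int8")
    if (r[1L] >= -32768 && r[2L] <= 32767) return("int16")
    if (r[1L] >= -2^31 && r[2L] < 2^31) return("int32")
  }
  "float64"
}

value_width <- function(type) {
  switch(type, int8 = 1L, int16 = 2L, int32 = 4L, float64 = 8L,
         stop("unknown value type: ", type, call. = FALSE))
}

## one width for every index, pointer and permutation array: the smallest
## of 16/32 bits that holds max(m, n, nnz)
index_width <- function(m, n, nnz) {
  if (max(m, n, nnz) < 65536) 2L else 4L
}

#' @export
print.casg_container <- function(x, ...) {
  cat(sprintf(
    "casg_container: codec=%s, %d x %d, nnz=%d, values=%s, %d bytes\n",
    x$codec, x$m, x$n, x$nnz, x$value_type, container_size_bytes(x)))
  invisible(x)
}

#' Decompress a container back to the original matrix
#'
#' Exact inverse of [compress()] for every codec: the stored arrays are
#' decoded and, for the reordering pipeline, the stored permutations are
#' inverted, so the result reproduces the input cell for cell, labels
#' included.
#'
#' @param C a `casg_container`.
#' @return a [mutation_matrix()].
#' @export
decompress <- function(C) {
  stopifnot(inherits(C, "casg_container"))
  m <- C$m
  n <- C$n
  A <- switch(C$codec,
    coo = as.matrix(coo_decode(new_coo(C$payload$i, C$payload$j,
                                       C$payload$values, m, n))),
    csc = as.matrix(csc_decode(new_csc(C$payload$indptr, C$payload$indices,
                                       C$payload$values, m, n))),
    casagm = {
      if (is.null(C$perms)) {
        stop("container is missing the permutations required to invert ",
             "the reordering", call. = FALSE)
      }
      ## compiled inverse of the pipeline: expands the renumbered CSR
      ## payload straight into the original row/column order, validating
      ## pointers and bounds as it goes
      casagm_invert_csr(C$payload$indptr, C$payload$indices,
                        C$payload$values, C$perms$row_perm,
                        C$perms$col_perm, m, n)
    },
    stop("unknown codec tag: ", C$codec, call. = FALSE))
  new_mm(A, C$labels)
}

#' Exact serialized size of a container, in bytes
#'
#' Closed-form byte count of the on-disk format: a fixed 21-byte header,
#' the codec's index and value arrays at the container's index/value
#' widths, the two permutation arrays for the reordering codec, and the
#' length-prefixed label block when labels are stored.  Always equals
#' `file.size()` of the file written by [write_casg()].
#'
#' @param C a `casg_container`.
#' @return integer byte count.
#' @export
container_size_bytes <- function(C) {
  stopifnot(inherits(C, "casg_container"))
  iw <- C$index_width
  vw <- value_width(C$value_type)
  k <- C$nnz
  idx <- switch(C$codec,
    coo = 2 * k * iw,
    csc = (C$n + 1L) * iw + k * iw,
    casagm = (C$m + 1L) * iw + k * iw)
  perm <- if (identical(C$codec, "casagm")) (C$m + C$n) * iw else 0L
  lab <- if (!is.null(C$labels)) {
    sum(2L + nchar(unlist(C$labels), type = "bytes"))
  } else {
    0L
  }
  as.integer(21L + idx + k * vw + perm + lab)
}
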