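#' Read a mutation matrix from a dense tab-separated file
#'
#' Expected layout: a header row with a corner cell followed by the gene
#' (column) labels, then one row per sample whose first field is the sample
#' label.  Empty cells are read as 0, the usual convention for level-3
#' mutation tables that are sparse by omission.
#'
#' @param path file path.
#' @return a [mutation_matrix()].
#' @export
read_dense_tsv <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) {
    stop("dense TSV needs a header row and at least one data row",
         call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n <- length(header) - 1L
  if (n < 1L) stop("header row has no column labels", call. = FALSE)
  col_labels <- header[-1L]
  m <- length(lines) - 1L
  row_labels <- character(m)
  values <- matrix(0, m, n)
  for (r in seq_len(m)) {
    f <- fields[[r + 1L]]
    if (length(f) != n + 1L) {
      stop(sprintf("ragged row on line %d: expected %d fields, found %d",
                   r + 1L, n + 1L, length(f)), call. = FALSE)
    }
    row_labels[r] <- f[1L]
    cells <- f[-1L]
    cells[cells == ""] <- "0"
    num <- suppressWarnings(as.numeric(cells))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1L]
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   f[1L], col_labels[bad], cells[bad]), call. = FALSE)
    }
    values[r, ] <- num
  }
  mutation_matrix(values, row_labels, col_labels)
}

#' Write a mutation matrix as a dense tab-separated file
#'
#' Inverse of [read_dense_tsv()]: `read_dense_tsv(write_dense_tsv(M, f))`
#' reproduces `M` exactly for integer-valued data and to full double
#' precision otherwise.  Output is byte-deterministic.
#'
#' @param M a [mutation_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dense_tsv <- function(M, path) {
  stopifnot(is_mutation_matrix(M))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(c("id", colnames(M)), collapse = "\t"),
               vapply(seq_len(nrow(M)), function(r) {
                 paste(c(rownames(M)[r], format_numeric(M[r, ])),
                       collapse = "\t")
               }, character(1))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## deterministic numeric formatting: integers without decimal point,
## reals with 17 significant digits (lossless for doubles)
format_numeric <- function(x) {
  out <- sprintf("%.17g", x)
  int <- x == trunc(x) & abs(x) < 2^53
  out[int] <- sprintf("%.0f", x[int])
  out
}

#' Read a mutation matrix from a MatrixMarket coordinate file
#'
#' Accepts `coordinate` files with `real`, `integer` or `pattern` fields and
#' `general` symmetry, 1-based indices per the standard.  Labels are not part
#' of the format, so default `S*` / `G*` labels are attached.
#'
#' @param path file path.
#' @return a [mutation_matrix()].
#' @export
read_matrix_market <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  banner <- readLines(path, n = 1L)
  if (!startsWith(banner, "%%MatrixMarket")) {
    stop("missing MatrixMarket banner in ", path, call. = FALSE)
  }
  parts <- strsplit(trimws(banner), "[[:space:]]+")[[1L]]
  if (length(parts) < 5L || parts[2L] != "matrix" || parts[3L] != "coordinate" ||
      !(parts[4L] %in% c("real", "integer", "pattern")) ||
      parts[5L] != "general") {
    stop("unsupported MatrixMarket qualifier: ",
         paste(parts[-1L], collapse = " "), call. = FALSE)
  }
  sm <- as.matrix(Matrix::readMM(path))
  mutation_matrix(sm)
}

#' Write a mutation matrix as a MatrixMarket coordinate file
#'
#' Writes 1-based coordinates in row-major order with a `real general` or
#' `integer general` banner depending on the values.  Labels are dropped
#' (the format has none).  Output is byte-deterministic.
#'
#' @param M a [mutation_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_market <- function(M, path) {
  stopifnot(is_mutation_matrix(M))
  tr <- dense_triplets(M)
  integral <- length(tr$v) == 0L || all(tr$v == trunc(tr$v) & abs(tr$v) < 2^31)
  field <- if (integral) "integer" else "real"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general", field),
               sprintf("%d %d %d", nrow(M), ncol(M), length(tr$v)),
               if (length(tr$v)) {
                 sprintf("%d %d %s", tr$i, tr$j, format_numeric(tr$v))
               }),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
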