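## On-disk container format (.casg), little-endian throughout:
##
##   offset  size  field
##   0       4     magic "CASG"
##   4       1     format version (1)
##   5       1     codec: 1 = coo, 2 = csc, 3 = casagm
##   6       1     flags: bit 0 = labels stored, bit 1 = permutations stored
##   7       1     value type: 1 = int8, 2 = int16, 3 = int32, 4 = float64
##   8       1     index width in bytes (2 or 4), shared by all index,
##                 pointer and permutation arrays
##   9       12    m, n, nnz as int32
##   21      ...   codec arrays:
##                   coo:    i[nnz], j[nnz], values[nnz]
##                   csc:    indptr[n+1], indices[nnz], values[nnz]
##                   casagm: indptr[m+1], indices[nnz], values[nnz]
##           ...   permutations (casagm): row_perm[m], col_perm[n], 0-based
##           ...   labels: for each of the m row then n column labels a
##                 uint16 byte length followed by the UTF-8 bytes
##
## No timestamps or platform fields: serialization is byte-deterministic.

CODEC_CODES <- c(coo = 1L, csc = 2L, casagm = 3L)
VALUE_CODES <- c(int8 = 1L, int16 = 2L, int32 = 3L, float64 = 4L)

#' Serialize a compressed container to disk
#'
#' Writes the deterministic binary `.casg` layout documented in the package
#' sources; `read_casg()` restores a field-identical container.  The file
#' length equals [container_size_bytes()] and is the compressed-memory
#' measurement used by [run_benchmark()].
#'
#' @param C a `casg_container` from [compress()].
#' @param path output path (conventional extension `.casg`).
#' @return `path`, invisibly.
#' @export
write_casg <- function(C, path) {
  stopifnot(inherits(C, "casg_container"))
  iw <- C$index_width
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw("CASG"), con)
  flags <- as.integer(!is.null(C$labels)) + 2L * as.integer(!is.null(C$perms))
  writeBin(as.integer(c(1L, CODEC_CODES[[C$codec]], flags,
                        VALUE_CODES[[C$value_type]], iw)),
           con, size = 1L, endian = "little")
  writeBin(c(C$m, C$n, C$nnz), con, size = 4L, endian = "little")
  wr_idx <- function(x) writeBin(as.integer(x), con, size = iw,
                                 endian = "little")
  switch(C$codec,
    coo = {
      wr_idx(C$payload$i)
      wr_idx(C$payload$j)
    },
    csc = {
      wr_idx(C$payload$indptr)
      wr_idx(C$payload$indices)
    },
    casagm = {
      wr_idx(C$payload$indptr)
      wr_idx(C$payload$indices)
    })
  if (C$value_type == "float64") {
    writeBin(as.double(C$payload$values), con, size = 8L, endian = "little")
  } else {
    writeBin(as.integer(C$payload$values), con,
             size = value_width(C$value_type), endian = "little")
  }
  if (!is.null(C$perms)) {
    wr_idx(C$perms$row_perm - 1L)
    wr_idx(C$perms$col_perm - 1L)
  }
  if (!is.null(C$labels)) {
    for (lab in c(C$labels[[1L]], C$labels[[2L]])) {
      b <- charToRaw(enc2utf8(lab))
      writeBin(length(b), con, size = 2L, endian = "little")
      writeBin(b, con)
    }
  }
  invisible(path)
}

#' Deserialize a compressed container from disk
#'
#' @param path a `.casg` file written by [write_casg()].
#' @return a `casg_container`, field-identical to the one serialized.
#' @export
read_casg <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(rawToChar(magic), "CASG")) {
    stop("not a casg container (bad magic): ", path, call. = FALSE)
  }
  hdr <- readBin(con, "integer", n = 5L, size = 1L, signed = FALSE,
                 endian = "little")
  if (length(hdr) < 5L) stop("truncated header in ", path, call. = FALSE)
  if (hdr[1L] != 1L) {
    stop("unsupported container version: ", hdr[1L], call. = FALSE)
  }
  codec <- names(CODEC_CODES)[match(hdr[2L], CODEC_CODES)]
  if (is.na(codec)) stop("unknown codec code: ", hdr[2L], call. = FALSE)
  has_labels <- bitwAnd(hdr[3L], 1L) > 0L
  has_perms <- bitwAnd(hdr[3L], 2L) > 0L
  vtype <- names(VALUE_CODES)[match(hdr[4L], VALUE_CODES)]
  if (is.na(vtype)) stop("unknown value-type code: ", hdr[4L], call. = FALSE)
  iw <- hdr[5L]
  if (!iw %in% c(2L, 4L)) stop("bad index width: ", iw, call. = FALSE)
  dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  if (length(dims) < 3L) stop("truncated header in ", path, call. = FALSE)
  m <- dims[1L]
  n <- dims[2L]
  k <- dims[3L]
  if (m < 1L || n < 1L || k < 0L || k > as.double(m) * n) {
    stop(sprintf("corrupt dimensions in %s: m=%d n=%d nnz=%d",
                 path, m, n, k), call. = FALSE)
  }
  rd_idx <- function(cnt, what) {
    x <- readBin(con, "integer", n = cnt, size = iw,
                 signed = iw > 2L, endian = "little")
    if (length(x) < cnt) {
      stop(sprintf("truncated container %s: %s has %d of %d entries",
                   path, what, length(x), cnt), call. = FALSE)
    }
    x
  }
  payload <- switch(codec,
    coo = list(i = rd_idx(k, "row indices"), j = rd_idx(k, "column indices")),
    csc = list(indptr = rd_idx(n + 1L, "indptr"),
               indices = rd_idx(k, "indices")),
    casagm = list(indptr = rd_idx(m + 1L, "indptr"),
                  indices = rd_idx(k, "indices")))
  vw <- value_width(vtype)
  v <- if (vtype == "float64") {
    readBin(con, "double", n = k, size = 8L, endian = "little")
  } else {
    as.double(readBin(con, "integer", n = k, size = vw,
                      signed = TRUE, endian = "little"))
  }
  if (length(v) < k) {
    stop(sprintf("truncated container %s: %d of %d values", path,
                 length(v), k), call. = FALSE)
  }
  payload$values <- v
  perms <- NULL
  if (has_perms) {
    perms <- list(row_perm = rd_idx(m, "row permutation") + 1L,
                  col_perm = rd_idx(n, "column permutation") + 1L)
    if (!setequal(perms$row_perm, seq_len(m)) ||
        !setequal(perms$col_perm, seq_len(n))) {
      stop("stored permutations are not valid bijections", call. = FALSE)
    }
  } else if (codec == "casagm") {
    stop("container is missing the permutations required to invert the ",
         "reordering", call. = FALSE)
  }
  labels <- NULL
  if (has_labels) {
    rd_lab <- function(cnt) {
      vapply(seq_len(cnt), function(q) {
        len <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                       endian = "little")
        if (length(len) < 1L) {
          stop("truncated label block in ", path, call. = FALSE)
        }
        b <- readBin(con, "raw", n = len)
        if (length(b) < len) {
          stop("truncated label block in ", path, call. = FALSE)
        }
        rawToChar(b)
      }, character(1))
    }
    labels <- list(rd_lab(m), rd_lab(n))
  }
  out <- structure(list(codec = codec, m = m, n = n, nnz = k,
                        value_type = vtype, index_width = iw,
                        payload = payload, perms = perms, labels = labels),
                   class = "casg_container")
  validate_container(out)
  out
}

validate_container <- function(C) {
  k <- C$nnz
  if (length(C$payload$values) != k) {
    stop("declared nnz does not match stored value count", call. = FALSE)
  }
  if (C$codec == "coo") {
    if (length(C$payload$i) != k || length(C$payload$j) != k) {
      stop("declared nnz does not match stored index count", call. = FALSE)
    }
  } else {
    axis <- if (C$codec == "csc") C$n else C$m
    check_compressed(C$payload$indptr, C$payload$indices, axis,
                     if (C$codec == "csc") C$m else C$n,
                     toupper(C$codec))
  }
  invisible(C)
}
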