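## Reverse Cuthill-McKee reordering.
##
## This file is the pure-R reference implementation of the reordering used
## by the compression pipeline; `compress()` runs an equivalent compiled
## kernel (src/rcm_pipeline.cpp) that is required to produce identical
## permutations, and the test suite asserts that equivalence.
##
## Tie rules, fixed for determinism:
##  * the traversal starts at the unvisited node of globally minimum degree,
##    lowest index first (no pseudo-peripheral search);
##  * neighbours enter the queue in increasing degree, ties by increasing
##    node index;
##  * exhausted components restart the search at the next unvisited
##    minimum-degree node.

#' Build the undirected graph of a matrix's non-zero pattern
#'
#' For a rectangular matrix the graph is bipartite: row `i` becomes node
#' `i`, column `j` becomes node `m + j`, and an edge joins them iff cell
#' `(i, j)` is non-zero.  For a square matrix the default is the symmetrised
#' pattern on the row nodes only: edge `(i, j)` iff `M[i, j]` or `M[j, i]`
#' is non-zero, diagonal entries dropped (they are self-loops and do not
#' count towards a node's degree).
#'
#' @param M a [mutation_matrix()] (or plain numeric matrix).
#' @param mode `"auto"` (symmetric for square input, bipartite otherwise),
#'   `"bipartite"` or `"symmetric"` (square input only).
#' @return an `adjacency_graph`: neighbour lists (sorted, unique), node
#'   count, and the row/column split when bipartite.
#' @export
build_adjacency <- function(M, mode = c("auto", "bipartite", "symmetric")) {
  mode <- match.arg(mode)
  tr <- dense_triplets(M)
  m <- tr$m
  n <- tr$n
  if (mode == "auto") mode <- if (m == n) "symmetric" else "bipartite"
  if (mode == "symmetric") {
    if (m != n) {
      stop("symmetric adjacency requires a square matrix", call. = FALSE)
    }
    keep <- tr$i != tr$j
    u <- c(tr$i[keep], tr$j[keep])
    v <- c(tr$j[keep], tr$i[keep])
    ## symmetrise and drop parallel edges
    key <- (u - 1) * as.double(n) + v
    first <- !duplicated(key)
    u <- u[first]
    v <- v[first]
    nodes <- m
  } else {
    u <- c(tr$i, m + tr$j)
    v <- c(m + tr$j, tr$i)
    nodes <- m + n
  }
  adj <- split(v, factor(u, levels = seq_len(nodes)))
  adj <- lapply(adj, function(x) sort.int(unique(x)))
  names(adj) <- NULL
  structure(list(adj = adj, n_nodes = nodes, mode = mode, m = m, n = n),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph (%s): %d nodes, %d edges\n", x$mode,
              x$n_nodes, sum(lengths(x$adj)) / 2))
  invisible(x)
}

#' Node degrees of an adjacency graph
#'
#' The degree of a node is the number of off-diagonal non-zeros linking it
#' to other nodes, i.e. the length of its neighbour list.
#'
#' @param G an `adjacency_graph` from [build_adjacency()].
#' @return integer vector of degrees.
#' @export
node_degrees <- function(G) {
  stopifnot(inherits(G, "adjacency_graph"))
  lengths(G$adj)
}

#' Cuthill-McKee ordering of a graph
#'
#' Breadth-first renumbering that keeps connected nodes close together.
#' Returns the ordering `R` as 1-based node indices: position `k` of the
#' result names the old node placed `k`-th.  The traversal is implemented
#' level-by-level, which yields exactly the classic queue order because the
#' queue processes parents in sequence and each parent appends its unvisited
#' neighbours in (degree, index) order.
#'
#' @param G an `adjacency_graph` from [build_adjacency()].
#' @return integer permutation of `1:n_nodes`.
#' @export
cuthill_mckee <- function(G) {
  stopifnot(inherits(G, "adjacency_graph"))
  N <- G$n_nodes
  deg <- lengths(G$adj)
  ## neighbour lists re-sorted by (degree, index) once, via one global sort
  u <- rep.int(seq_len(N), deg)
  v <- unlist(G$adj, use.names = FALSE)
  if (length(v)) {
    o <- order(u, deg[v], v, method = "radix")
    vs <- v[o]
  } else {
    vs <- integer(0)
  }
  ptr <- c(0L, cumsum(deg))
  Rv <- integer(N)
  visited <- logical(N)
  r <- 0L
  iso <- which(deg == 0L)          # all isolated nodes carry the minimum
  if (length(iso)) {               # degree, so they are placed first,
    Rv[seq_along(iso)] <- iso      # lowest index first
    visited[iso] <- TRUE
    r <- length(iso)
  }
  so <- order(deg, seq_len(N), method = "radix")
  sp <- 1L
  while (r < N) {
    while (visited[so[sp]]) sp <- sp + 1L
    lvl <- so[sp]
    visited[lvl] <- TRUE
    while (length(lvl)) {
      Rv[(r + 1L):(r + length(lvl))] <- lvl
      r <- r + length(lvl)
      ch <- vs[sequence(deg[lvl], from = ptr[lvl] + 1L)]
      ch <- ch[!visited[ch]]
      ch <- ch[!duplicated(ch)]
      visited[ch] <- TRUE
      lvl <- ch
    }
  }
  Rv
}

#' Reverse an ordering
#'
#' The "reverse" step of reverse Cuthill-McKee: element `k` of the output is
#' element `length(R) + 1 - k` of the input.  An involution.
#'
#' @param R an ordering (integer permutation).
#' @return the reversed ordering.
#' @export
reverse_ordering <- function(R) rev(R)

#' Row and column permutations from reverse Cuthill-McKee
#'
#' Runs [cuthill_mckee()] on the matrix's graph, reverses the ordering, and
#' converts it into row and column renumberings.  For a square matrix
#' (symmetric mode) rows and columns share one permutation; for a
#' rectangular matrix the bipartite ordering is split into its row-node and
#' column-node subsequences.
#'
#' Permutations are returned in old-to-new convention:
#' `row_perm[i]` is the new position of old row `i`, so the reordered
#' matrix is `M[order(row_perm), order(col_perm)]` (see
#' [apply_permutations()]).
#'
#' @param M a [mutation_matrix()] (or plain numeric matrix).
#' @param mode passed to [build_adjacency()].
#' @return a `permutation_pair` with elements `row_perm` and `col_perm`.
#' @export
rcm_permutations <- function(M, mode = c("auto", "bipartite", "symmetric")) {
  G <- build_adjacency(M, mode)
  Rv <- reverse_ordering(cuthill_mckee(G))
  m <- G$m
  n <- G$n
  if (G$mode == "symmetric") {
    rp <- integer(m)
    rp[Rv] <- seq_len(m)
    pp <- list(row_perm = rp, col_perm = rp)
  } else {
    rn <- Rv[Rv <= m]
    cn <- Rv[Rv > m] - m
    rp <- integer(m)
    rp[rn] <- seq_len(m)
    cp <- integer(n)
    cp[cn] <- seq_len(n)
    pp <- list(row_perm = rp, col_perm = cp)
  }
  structure(pp, class = "permutation_pair")
}

#' @export
print.permutation_pair <- function(x, ...) {
  cat(sprintf("permutation_pair: %d rows, %d columns\n",
              length(x$row_perm), length(x$col_perm)))
  invisible(x)
}

#' Apply or invert a permutation pair
#'
#' `apply_permutations(M, pp)` moves old row `i` to row `pp$row_perm[i]`
#' (and likewise columns); `invert_permutations(pp)` returns the pair that
#' undoes it, so applying both is the identity.
#'
#' @param M a [mutation_matrix()] (or plain numeric matrix).
#' @param pp a `permutation_pair`.
#' @return the reordered matrix / the inverse `permutation_pair`.
#' @export
apply_permutations <- function(M, pp) {
  stopifnot(inherits(pp, "permutation_pair"))
  A <- as.matrix(M)[order(pp$row_perm), order(pp$col_perm), drop = FALSE]
  mutation_matrix(A)
}

#' @rdname apply_permutations
#' @export
invert_permutations <- function(pp) {
  stopifnot(inherits(pp, "permutation_pair"))
  structure(list(row_perm = order(pp$row_perm), col_perm = order(pp$col_perm)),
            class = "permutation_pair")
}

#' Bandwidth of a non-zero pattern
#'
#' For a square matrix, the widest diagonal distance `max |i - j|` over the
#' non-zero cells.  A rectangular matrix is measured on its symmetric
#' `(m + n) x (m + n)` bipartite pattern, where cell `(i, j)` sits at
#' position `(i, m + j)`.  An all-zero pattern has bandwidth 0.
#'
#' @param M a matrix (any numeric matrix; a [mutation_matrix()] works).
#' @return integer bandwidth.
#' @export
bandwidth <- function(M) {
  tr <- dense_triplets(M)
  if (length(tr$i) == 0L) return(0L)
  if (tr$m == tr$n) {
    max(abs(tr$i - tr$j))
  } else {
    max(abs(tr$i - (tr$m + tr$j)))
  }
}
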