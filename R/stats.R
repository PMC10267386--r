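#' Paired-sample t test
#'
#' Two-sided paired t test on equal-length metric vectors: with
#' `d = x - y`, the statistic is `mean(d) / (sd(d) / sqrt(n))` referred to a
#' Student t distribution with `n - 1` degrees of freedom.  Used to compare
#' one evaluation metric between two codecs across the same datasets.
#'
#' @param x,y paired numeric vectors of equal length (at least 2).
#' @return an object of class `htest`.
#' @examples
#' paired_t_test(c(2, 4, 6), c(1, 2, 3))
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  s <- sd(d)
  if (s == 0) {
    stop("degenerate input: paired differences have zero variance",
         call. = FALSE)
  }
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1L)
  structure(list(statistic = c(t = t), parameter = c(df = n - 1L),
                 p.value = p, estimate = c(`mean difference` = mean(d)),
                 alternative = "two.sided",
                 method = "Paired t-test",
                 data.name = paste(deparse1(substitute(x)), "vs",
                                   deparse1(substitute(y)))),
            class = "htest")
}

#' Tie-aware Spearman rank correlation
#'
#' Computes `rho` as the Pearson correlation of average-assigned ranks.  The
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom
#' (the usual choice at the small n of per-dataset benchmark tables); for
#' `n <= 8` an exact permutation p-value is available.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @param method `"asymptotic"` (t approximation) or `"exact"` (full
#'   permutation enumeration, `n <= 8`).
#' @return an object of class `htest` with `estimate` rho.
#' @examples
#' spearman_test(1:5, c(5, 6, 7, 8, 7))
#' @export
spearman_test <- function(x, y, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- rank_pearson(rx, ry)
  if (method == "exact") {
    if (n > 8L) {
      stop("exact permutation p-value supported for n <= 8", call. = FALSE)
    }
    perms <- all_perms(n)
    rhos <- apply(perms, 1L, function(p) rank_pearson(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    denom <- 1 - rho^2
    p <- if (denom < .Machine$double.eps) {
      0
    } else {
      t <- rho * sqrt((n - 2) / denom)
      2 * pt(-abs(t), df = n - 2L)
    }
  }
  structure(list(statistic = c(S = sum((rx - ry)^2)),
                 p.value = p, estimate = c(rho = rho),
                 alternative = "two.sided",
                 method = sprintf("Spearman rank correlation (%s)", method),
                 data.name = paste(deparse1(substitute(x)), "vs",
                                   deparse1(substitute(y)))),
            class = "htest")
}

rank_pearson <- function(rx, ry) {
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Mean and standard deviation by group
#'
#' Summarises numeric columns as mean and sample standard deviation
#' (denominator `n - 1`) within groups -- the format used by benchmark
#' reports.  Groups with fewer than 2 observations are kept with `NA`
#' standard deviation, empty groups are dropped with a warning.
#'
#' @param df a data.frame (e.g. benchmark records or dataset profiles).
#' @param metrics character vector of numeric column names to summarise
#'   (default: all numeric columns outside `by`).
#' @param by optional name of a grouping column; `NULL` summarises the whole
#'   table as one group.
#' @return a long data.frame with columns `group`, `metric`, `mean`, `sd`,
#'   `n`.
#' @export
summarize_metrics <- function(df, metrics = NULL, by = NULL) {
  stopifnot(is.data.frame(df))
  if (is.null(metrics)) {
    metrics <- names(df)[vapply(df, is.numeric, logical(1))]
    metrics <- setdiff(metrics, by)
  }
  groups <- if (is.null(by)) {
    list(all = seq_len(nrow(df)))
  } else {
    split(seq_len(nrow(df)), df[[by]])
  }
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning("dropping empty groups: ", paste(names(groups)[empty],
                                             collapse = ", "))
    groups <- groups[!empty]
  }
  out <- do.call(rbind, lapply(names(groups), function(g) {
    rows <- groups[[g]]
    data.frame(group = g, metric = metrics,
               mean = vapply(metrics, function(mc) mean(df[rows, mc]),
                             double(1)),
               sd = vapply(metrics, function(mc) {
                 if (length(rows) < 2L) NA_real_ else sd(df[rows, mc])
               }, double(1)),
               n = length(rows), row.names = NULL)
  }))
  out
}
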