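## Benchmark harness.
##
## Metric definitions, per dataset and codec:
##   CT  = compression wall time (ms): start-to-end of compress()
##   DCT = decompression wall time (ms): start-to-end of decompress()
##   CR  = pre-compression size / CT   (MB/s, MB = 1e6 bytes)
##   DCR = decompressed size / DCT     (MB/s)
##   CM  = serialized container size (bytes)
##   CRO = pre-compression size / CM   (dimensionless)
## "Pre-compression size" is the in-memory dense representation,
## 8 bytes per cell.  Times are medians over repetitions after one
## discarded warm-up run; operations faster than the sampling floor are
## batched in an inner loop and the per-call time reported.  The timer is
## the monotonic process clock (resolution 1 ms on this platform).
## A cell's timings are only reported after its decompressed output has
## been verified equal to the input -- a lossy run aborts the benchmark.

TIMER_RESOLUTION_S <- 0.001

## one warm-up call; returns its result, its elapsed time, and the inner
## batching factor that keeps a timed sample above the sampling floor
warm_up <- function(fn, min_sample_s = 0.02) {
  t0 <- proc.time()[[3L]]
  result <- fn()
  warm <- proc.time()[[3L]] - t0
  inner <- if (warm >= min_sample_s) {
    1L
  } else {
    min(1000L, as.integer(ceiling(min_sample_s / max(warm, 1e-5))))
  }
  list(result = result, inner = inner)
}

one_sample <- function(fn, inner) {
  gc(FALSE)              # keep collector pauses out of the timed window
  t0 <- proc.time()[[3L]]
  for (z in seq_len(inner)) fn()
  (proc.time()[[3L]] - t0) / inner
}

#' Benchmark the codecs on a set of matrices
#'
#' Runs every codec on every dataset and reports the six evaluation
#' metrics: compression and decompression time (`ct_ms`, `dct_ms`, medians
#' over `repetitions` after a discarded warm-up), compression and
#' decompression rate (`cr_mbps`, `dcr_mbps`), compressed memory
#' (`cm_bytes`, the serialized container size) and compression ratio
#' (`cro`, dense bytes over compressed bytes).  Before any timing is
#' accepted the round trip is verified cell for cell; a mismatch aborts
#' with an error rather than reporting timings for a lossy run.
#'
#' @param datasets a named list of [mutation_matrix()] objects.
#' @param codecs subset of `c("coo", "csc", "casagm")`.
#' @param repetitions timed repetitions per cell (default 11).
#' @param seed optional seed; when given, the codec order within each
#'   repetition round is rotated from a seeded start.
#' @details Repetition rounds are blocked: within one dataset, round `r`
#'   times every codec once before round `r + 1` starts, so slow drift in
#'   machine speed lands on all codecs alike instead of biasing whichever
#'   was measured last.  Medians are taken over rounds.
#' @return a data.frame of class `benchmark_records`, one row per
#'   dataset-codec cell.
#' @export
run_benchmark <- function(datasets, codecs = c("coo", "csc", "casagm"),
                          repetitions = 11L, seed = NULL) {
  codecs <- match.arg(codecs, several.ok = TRUE)
  stopifnot(repetitions >= 1L, length(datasets) >= 1L)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  offset <- if (is.null(seed)) 0L else sample_with_seed(length(codecs), seed)[1L]
  rows <- list()
  for (ds in names(datasets)) {
    M <- datasets[[ds]]
    stopifnot(is_mutation_matrix(M))
    pre_bytes <- 8 * nrow(M) * ncol(M)
    cell <- list()
    for (codec in codecs) {
      cfun <- local({
        cd <- codec
        function() compress(M, cd, store_labels = FALSE)
      })
      wc <- warm_up(cfun)
      container <- wc$result
      recovered <- decompress(container)
      if (!identical(unname(as.matrix(recovered)), unname(as.matrix(M)))) {
        stop(sprintf("lossy round trip for dataset '%s', codec '%s': %s",
                     ds, codec, "benchmark aborted"), call. = FALSE)
      }
      dfun <- local({
        cont <- container
        function() decompress(cont)
      })
      wd <- warm_up(dfun)
      cell[[codec]] <- list(container = container, cfun = cfun, dfun = dfun,
                            inner_c = wc$inner, inner_d = wd$inner,
                            ct = double(repetitions),
                            dct = double(repetitions))
    }
    for (r in seq_len(repetitions)) {
      ord <- codecs[(seq_along(codecs) + offset + r - 2L) %%
                      length(codecs) + 1L]
      for (codec in ord) {
        cell[[codec]]$ct[r] <- one_sample(cell[[codec]]$cfun,
                                          cell[[codec]]$inner_c)
      }
      for (codec in ord) {
        cell[[codec]]$dct[r] <- one_sample(cell[[codec]]$dfun,
                                           cell[[codec]]$inner_d)
      }
    }
    for (codec in codecs) {
      tmp <- tempfile(fileext = ".casg")
      write_casg(cell[[codec]]$container, tmp)
      cm <- file.size(tmp)
      unlink(tmp)
      ct_s <- median(cell[[codec]]$ct)
      dct_s <- median(cell[[codec]]$dct)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, codec = codec,
        ct_ms = ct_s * 1e3, dct_ms = dct_s * 1e3,
        cr_mbps = (pre_bytes / 1e6) / ct_s,
        dcr_mbps = (pre_bytes / 1e6) / dct_s,
        cm_bytes = cm, cro = pre_bytes / cm,
        pre_bytes = pre_bytes,
        repetitions = repetitions,
        inner_comp = cell[[codec]]$inner_c,
        inner_decomp = cell[[codec]]$inner_d,
        timer_resolution_s = TIMER_RESOLUTION_S)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("benchmark_records", class(out))
  out
}

#' Correlate benchmark metrics with dataset characteristics
#'
#' Spearman rank correlation ([spearman_test()]) of each evaluation metric
#' against each dataset characteristic, per codec -- the analysis used to
#' ask which property of the raw data (non-zero count, sparsity, file
#' size, norms, ...) drives compression behaviour.
#'
#' @param records a `benchmark_records` data.frame from [run_benchmark()].
#' @param profiles a data.frame of dataset characteristics with a `dataset`
#'   column matching `records$dataset` (e.g. rows of [profile_dataset()]).
#' @param metrics metric columns of `records` to correlate.
#' @param characteristics characteristic columns of `profiles` to correlate
#'   against (default: all numeric columns).
#' @return a long data.frame with columns `codec`, `metric`,
#'   `characteristic`, `rho`, `p_value`.
#' @export
correlate_with_profiles <- function(records, profiles,
                                    metrics = c("ct_ms", "dct_ms", "cr_mbps",
                                                "dcr_mbps", "cm_bytes",
                                                "cro"),
                                    characteristics = NULL) {
  stopifnot("dataset" %in% names(profiles))
  if (is.null(characteristics)) {
    characteristics <- names(profiles)[vapply(profiles, is.numeric,
                                              logical(1))]
  }
  out <- list()
  for (codec in unique(records$codec)) {
    rec <- records[records$codec == codec, , drop = FALSE]
    prof <- profiles[match(rec$dataset, profiles$dataset), , drop = FALSE]
    for (mc in metrics) {
      for (ch in characteristics) {
        ok <- is.finite(prof[[ch]])
        res <- tryCatch(spearman_test(rec[[mc]][ok], prof[[ch]][ok]),
                        error = function(e) NULL)
        out[[length(out) + 1L]] <- data.frame(
          codec = codec, metric = mc, characteristic = ch,
          rho = if (is.null(res)) NA_real_ else unname(res$estimate),
          p_value = if (is.null(res)) NA_real_ else res$p.value)
      }
    }
  }
  do.call(rbind, out)
}

sample_with_seed <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  sample.int(n)
}
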