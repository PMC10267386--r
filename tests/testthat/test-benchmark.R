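test_that("benchmark records satisfy the metric identities", {
  ds <- list(a = generate_matrix(30, 60, 10, seed = 1),
             b = generate_matrix(25, 40, 4, seed = 2))
  rec <- run_benchmark(ds, repetitions = 3, seed = 1)
  expect_identical(nrow(rec), 6L)
  expect_true(all(rec$ct_ms > 0))
  expect_true(all(rec$dct_ms > 0))
  expect_true(all(rec$cm_bytes > 0))
  ## CRO is exactly pre-compression bytes over compressed bytes
  expect_equal(rec$cro, rec$pre_bytes / rec$cm_bytes)
  ## rate times time recovers the input size (unit consistency)
  expect_equal(rec$cr_mbps * rec$ct_ms / 1e3, rec$pre_bytes / 1e6)
  expect_equal(rec$dcr_mbps * rec$dct_ms / 1e3, rec$pre_bytes / 1e6)
  ## CM equals the closed-form container size
  for (q in seq_len(nrow(rec))) {
    cc <- compress(ds[[rec$dataset[q]]], rec$codec[q], store_labels = FALSE)
    expect_identical(as.integer(rec$cm_bytes[q]), container_size_bytes(cc))
  }
})

test_that("storage footprints order as the index layouts predict", {
  ## below one non-zero per column the dual-index COO stream is smaller
  ## than CSC's pointer array; CRO orders the other way around
  sparse <- generate_matrix(80, 3000, sparsity_pct = 0.5, seed = 3)
  cm <- vapply(c("coo", "csc", "casagm"), function(cd) {
    container_size_bytes(compress(sparse, cd, store_labels = FALSE))
  }, integer(1))
  expect_lt(cm[["coo"]], cm[["csc"]])
  pre <- 8 * nrow(sparse) * ncol(sparse)
  expect_gt(pre / cm[["coo"]], pre / cm[["csc"]])

  ## at CNV-like density the pointer-based layouts converge (< 5% apart)
  dense <- generate_matrix(120, 3000, sparsity_pct = 25,
                           value_model = "cnv_signed", seed = 4)
  cmd <- vapply(c("csc", "casagm"), function(cd) {
    container_size_bytes(compress(dense, cd, store_labels = FALSE))
  }, integer(1))
  expect_lt(abs(cmd[["csc"]] - cmd[["casagm"]]) / cmd[["csc"]], 0.05)
})

test_that("the harness rejects codecs it cannot verify", {
  expect_error(run_benchmark(list(x = random_mm(1)), codecs = "lzw"))
  expect_error(run_benchmark(list(), repetitions = 1))
})

test_that("paired t test matches its closed form and flags degenerate input", {
  ht <- paired_t_test(c(2, 4, 6), c(1, 2, 3))  # d = 1, 2, 3
  expect_equal(unname(ht$statistic), 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(ht$p.value, 0.0742, tolerance = 1e-3)
  expect_error(paired_t_test(1:4, 1:4), "degenerate")
  expect_error(paired_t_test(1:4 + 2, 1:4), "degenerate")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("spearman correlation is tie-aware and sign-correct", {
  expect_equal(unname(spearman_test(1:6, c(2, 4, 5, 9, 11, 30))$estimate), 1)
  expect_equal(unname(spearman_test(1:6, rev(1:6))$estimate), -1)
  ## ties: average ranks give rho = 8 / sqrt(10 * 9.5)
  st <- spearman_test(1:5, c(5, 6, 7, 8, 7))
  expect_equal(unname(st$estimate), 0.821, tolerance = 5e-4)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 2:3), "at least 3")
  ## exact enumeration agrees with the observed statistic's extremity
  se <- spearman_test(1:5, c(2, 1, 4, 3, 5), method = "exact")
  expect_gte(se$p.value, 0)
  expect_lte(se$p.value, 1)
  expect_identical(unname(se$estimate),
                   unname(spearman_test(1:5, c(2, 1, 4, 3, 5))$estimate))
})

test_that("test statistics agree with the stats-package reference", {
  set.seed(10)
  for (q in 1:15) {
    x <- rnorm(8)
    y <- rnorm(8) + 0.3
    ht <- paired_t_test(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(unname(ht$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(ht$p.value, ref$p.value, tolerance = 1e-12)
    xt <- round(rnorm(9), 1)  # induce ties
    yt <- round(rnorm(9), 1)
    if (length(unique(xt)) > 1 && length(unique(yt)) > 1) {
      st <- spearman_test(xt, yt)
      refs <- suppressWarnings(cor.test(xt, yt, method = "spearman",
                                        exact = FALSE))
      expect_equal(unname(st$estimate), unname(refs$estimate),
                   tolerance = 1e-12)
      expect_equal(st$p.value, refs$p.value, tolerance = 1e-12)
    }
  }
})

test_that("group summaries reproduce the published table means", {
  snv <- snv_regimes()
  s <- summarize_metrics(snv, metrics = "sparsity_pct")
  expect_equal(round(s$mean, 2), 0.55)
  expect_identical(s$n, 9L)
  cnv <- cnv_regimes()
  s2 <- summarize_metrics(cnv, metrics = "sparsity_pct")
  expect_equal(round(s2$mean, 2), 19.58)
  expect_equal(round(summarize_metrics(snv,
                                       metrics = "rows_over_cols_pct")$mean,
               2), 2.39)
  ## a constant group has zero standard deviation
  df <- data.frame(g = c("a", "a", "a"), v = c(2, 2, 2))
  s3 <- summarize_metrics(df, metrics = "v", by = "g")
  expect_identical(s3$sd, 0)
  ## empty factor levels are dropped with a warning
  df2 <- data.frame(g = factor(c("a", "a"), levels = c("a", "b")), v = 1:2)
  expect_warning(summarize_metrics(df2, metrics = "v", by = "g"), "empty")
})

test_that("metric-characteristic correlations recover known monotone links", {
  profiles <- data.frame(dataset = paste0("d", 1:6),
                         nnz = c(10, 50, 200, 800, 3000, 9000))
  records <- data.frame(dataset = paste0("d", 1:6),
                        codec = "coo",
                        ct_ms = c(1, 2, 5, 9, 20, 44),
                        dct_ms = 1, cr_mbps = 1, dcr_mbps = 1,
                        cm_bytes = 1, cro = c(50, 40, 30, 20, 10, 5))
  out <- correlate_with_profiles(records, profiles,
                                 metrics = c("ct_ms", "cro"),
                                 characteristics = "nnz")
  expect_equal(out$rho[out$metric == "ct_ms"], 1)
  expect_equal(out$rho[out$metric == "cro"], -1)
})
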