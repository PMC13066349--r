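test_that("expected counts follow the background proportion", {
  expect_equal(round_half_up(expected_count(80, 3203, 19504), 2), 13.14)
  expect_equal(round_half_up(expected_count(67, 152, 420), 2), 24.25)
  expect_equal(expected_count(50, 0, 1000), 0)
  expect_error(expected_count(10, 5, 0), "background_total")
  expect_error(expected_count(10, 20, 15), "background_in")
})

test_that("two-cell goodness of fit matches the stats::chisq.test oracle", {
  grid <- expand.grid(obs = c(1, 5, 13, 37, 45, 79), n = c(80, 420))
  grid <- grid[grid$obs < grid$n, ]
  for (i in seq_len(nrow(grid))) {
    obs <- grid$obs[i]
    n <- grid$n[i]
    expd <- 0.3 * n
    got <- gof_chi2(obs, expd, n)
    want <- suppressWarnings(
      stats::chisq.test(c(obs, n - obs), p = c(0.3, 0.7), correct = FALSE)
    )
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, unname(want$p.value), tolerance = 1e-12)
  }
  zero <- gof_chi2(24, 24, 80)
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p.value, 1)
  expect_identical(zero$direction, "none")
  expect_error(gof_chi2(5, 0, 80), "strictly between")
  expect_error(gof_chi2(5, 80, 80), "strictly between")
})

test_that("gof p-value decreases as observed moves away from expected", {
  ps <- vapply(seq(25, 70, by = 5),
               function(o) gof_chi2(o, 24, 80)$p.value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("2x2 partition test preserves margins and matches chisq.test", {
  genes <- tibble::tibble(
    low_di = rep(c(TRUE, FALSE), times = c(45, 35)),
    dev = c(rep(TRUE, 18), rep(FALSE, 27), rep(TRUE, 5), rep(FALSE, 30))
  )
  res <- partition_2x2_test(genes, ~low_di, ~dev)
  expect_equal(as.vector(res$expected),
               c(12.9375, 10.0625, 32.0625, 24.9375), tolerance = 1e-12)
  expect_equal(rowSums(res$expected), rowSums(res$observed), tolerance = 1e-12)
  expect_equal(colSums(res$expected), colSums(res$observed), tolerance = 1e-12)
  want <- stats::chisq.test(res$observed, correct = FALSE)
  expect_equal(res$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(res$p.value, unname(want$p.value), tolerance = 1e-12)
  expect_lt(res$p.value, 0.05)

  flat <- tibble::tibble(a = rep(c(TRUE, FALSE), 20), b = rep(c(TRUE, FALSE), 20))
  expect_equal(partition_2x2_test(flat, ~a, ~b)$statistic, 40 * 1,
               tolerance = 1e-9) # perfectly dependent
  indep <- tibble::tibble(
    a = rep(c(TRUE, TRUE, FALSE, FALSE), 10),
    b = rep(c(TRUE, FALSE, TRUE, FALSE), 10)
  )
  expect_equal(partition_2x2_test(indep, ~a, ~b)$statistic, 0, tolerance = 1e-12)
  onecol <- tibble::tibble(a = c(TRUE, FALSE), b = c(TRUE, TRUE))
  expect_error(partition_2x2_test(onecol, ~a, ~b), "Zero margin")
})

test_that("threshold share is inclusive at the cut and rounds like the reports", {
  sh <- threshold_share(c(rep(0.1, 45), rep(0.5, 35)), 0.25)
  expect_identical(sh$count, 45L)
  expect_equal(sh$percent, 56.3)
  expect_equal(threshold_share(c(0.3, 0.4), 0.25)$percent, 0)
  expect_identical(threshold_share(c(0.25, 0.26), 0.25)$count, 1L)
  expect_error(threshold_share(numeric(), 0.25), "empty input")
})

test_that("di_histogram bins are right-closed and percentages sum to 100", {
  h <- di_histogram(c(0.05, 0.051, 0.1, 0.9), bin_width = 0.05)
  expect_equal(sum(h$percent), 100, tolerance = 1e-9)
  expect_identical(h$n[1], 1L) # 0.05 falls in (0, 0.05]
  expect_identical(sum(h$n), 4L)
  expect_error(di_histogram(numeric()), "empty input")
})

test_that("binomial upper tail agrees with direct summation", {
  cases <- list(c(8, 11, 0.1642), c(3, 10, 0.5), c(1, 4, 0.2))
  for (cs in cases) {
    expect_equal(binomial_tail(cs[1], cs[2], cs[3]),
                 oracle_binom_tail(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
  expect_equal(binomial_tail(0, 11, 0.3), 1)
  expect_equal(binomial_tail(11, 11, 0.3), 0.3^11, tolerance = 1e-12)
})

test_that("enrich excludes genes with missing category values from both margins", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40),
    di = c(rep(0.1, 10), rep(0.6, 20), rep(NA, 10))
  )
  set <- gene_set(genes$gene_id[c(1:5, 31:35)], "small")
  bg <- gene_set(genes$gene_id, "all")
  res <- enrich(genes, set, bg, ~ di <= 0.25)
  expect_identical(res$n, 5L) # the 5 NA members dropped
  expect_identical(res$observed, 5L)
  expect_identical(res$n_missing_set, 5L)
  expect_identical(res$background_total, 30L)
  expect_equal(res$expected, 5 * 10 / 30, tolerance = 1e-12)
})
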