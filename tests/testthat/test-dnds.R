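test_that("estimate_dnds reproduces the single-synonymous-change case exactly", {
  est <- estimate_dnds("TTTGCTAAA", "TTCGCTAAA")
  expect_equal(est$sd, 1)
  expect_equal(est$nd, 0)
  expect_equal(est$s_sites, 5 / 3, tolerance = 1e-12)
  expect_equal(est$n_sites, 9 - 5 / 3, tolerance = 1e-12)
  expect_equal(est$ps, 0.6, tolerance = 1e-12)
  expect_equal(est$ds, -0.75 * log(1 - 0.8), tolerance = 1e-12)
  expect_equal(est$dn, 0)
  expect_equal(est$ratio, 0)
})

test_that("identical pair gives zero divergence and undefined ratio", {
  est <- estimate_dnds("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(est$nd + est$sd, 0)
  expect_equal(est$dn, 0)
  expect_equal(est$ds, 0)
  expect_true(is.na(est$ratio))
})

test_that("nonsynonymous-only divergence leaves the ratio undefined (dS = 0)", {
  # ATG -> CTG and ATG -> AGG are nonsynonymous first/second-position changes
  est <- estimate_dnds("ATGATGGCT", "CTGAGGGCT")
  expect_equal(est$sd, 0)
  expect_gt(est$nd, 0)
  expect_true(is.na(est$ratio))
})

test_that("gap and ambiguity columns are discarded; degenerate inputs error", {
  est <- estimate_dnds("TTT---AAA", "TTTGCTAAA")
  expect_identical(est$n_codons, 2L)
  expect_identical(est$n_discarded, 1L)
  expect_error(estimate_dnds("---", "AAA"), "zero usable columns")
  expect_error(estimate_dnds("TTTTAA", "TTTTAA"), "stop")
  expect_error(estimate_dnds("TTTT", "TTTT"), "multiple of 3")
  expect_error(estimate_dnds("TTT", "TTTTTT"), "equal length")
})

test_that("saturated proportions are refused rather than corrected", {
  # 61 maximally different synonymous-rich columns is hard to build;
  # force saturation with many synonymous third-position changes over
  # few codons: CTA/CTG pairs are synonymous Leu columns
  seq_a <- strrep("CTA", 5)
  seq_b <- strrep("CTG", 5)
  expect_error(estimate_dnds(seq_a, seq_b), "saturation")
})

test_that("estimates are symmetric and invariant to column order", {
  set.seed(11)
  codons <- sense_codons()
  a <- paste(sample(codons, 40, replace = TRUE), collapse = "")
  b <- paste(sample(codons, 40, replace = TRUE), collapse = "")
  ab <- estimate_dnds(a, b)
  ba <- estimate_dnds(b, a)
  expect_equal(ab[, -(1:2)], ba[, -(1:2)], tolerance = 1e-12)

  perm <- sample(40)
  pa <- paste(substring(a, 3 * perm - 2, 3 * perm), collapse = "")
  pb <- paste(substring(b, 3 * perm - 2, 3 * perm), collapse = "")
  expect_equal(estimate_dnds(pa, pb)[, -(1:2)], ab[, -(1:2)],
               tolerance = 1e-12)
})

test_that("site conservation holds across random alignments", {
  set.seed(13)
  codons <- sense_codons()
  for (i in 1:10) {
    len <- sample(5:50, 1)
    a <- paste(sample(codons, len, replace = TRUE), collapse = "")
    b <- paste(sample(codons, len, replace = TRUE), collapse = "")
    est <- tryCatch(estimate_dnds(a, b), error = function(e) NULL)
    if (is.null(est)) next # saturated draw
    expect_equal(est$n_sites + est$s_sites, 3 * len, tolerance = 1e-9)
  }
})

test_that("DI is the mean of defined pair ratios with undefined pairs excluded", {
  est <- tibble::tibble(
    gene_id = "g1",
    species = c("Pan troglodytes", "Pan paniscus", "Gorilla gorilla gorilla"),
    ratio = c(0.4, NA, 0.2)
  )
  di <- compute_di(est)
  expect_equal(di$di, 0.3)
  expect_identical(di$n_used, 2L)
  expect_identical(di$selection_class, "stabilizing")

  allsame <- tibble::tibble(gene_id = "g", species = letters[1:4],
                            ratio = rep(0.2, 4))
  expect_equal(compute_di(allsame)$di, 0.2)

  none <- tibble::tibble(gene_id = "g", species = "a", ratio = NA_real_)
  out <- compute_di(none)
  expect_true(is.na(out$di))
  expect_identical(out$n_used, 0L)
  expect_identical(out$selection_class, "undefined")

  dup <- tibble::tibble(gene_id = "g", species = c("a", "a"), ratio = c(1, 2))
  expect_error(compute_di(dup), "Duplicate species")
})

test_that("selection classification follows the neutrality band", {
  expect_identical(
    classify_selection(c(1.84, 1.0, 0.026, NA)),
    c("diversifying", "neutral", "stabilizing", "undefined")
  )
  expect_identical(classify_selection(0.9), "neutral")
  expect_identical(classify_selection(1.1), "neutral")
  expect_identical(classify_selection(0.95, c(0.99, 1.01)), "stabilizing")
  expect_error(classify_selection(-0.1), "non-negative")
})
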