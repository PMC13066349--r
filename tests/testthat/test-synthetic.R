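test_that("universe generation is reproducible under a fixed seed", {
  a <- generate_universe(200, seed = 123)
  b <- generate_universe(200, seed = 123)
  expect_identical(a$genes, b$genes)
  expect_identical(a$hits, b$hits)
  c <- generate_universe(200, seed = 124)
  expect_false(identical(a$genes, c$genes))
})

test_that("a degenerate PAI distribution lands every gene at its rank", {
  probs <- rep(0, 16)
  probs[6] <- 1
  u <- generate_universe(300, pai_probabilities = probs, seed = 5)
  recovered <- assign_pai(u$hits, u$species_map, u$ladder,
                          gene_ids = u$genes$gene_id)
  expect_true(all(recovered$pai == 6L))
})

test_that("assign_pai recovers every planted PAI exactly, decoys and extras included", {
  u <- generate_universe(1500, seed = 99)
  recovered <- assign_pai(u$hits, u$species_map, u$ladder,
                          gene_ids = u$genes$gene_id)
  merged <- dplyr::left_join(u$genes, recovered, by = "gene_id",
                             suffix = c("_planted", "_recovered"))
  expect_identical(merged$pai_recovered, merged$pai_planted)
})

test_that("invalid generator specifications are rejected", {
  expect_error(generate_universe(10, pai_probabilities = rep(0.1, 16)),
               "summing to 1")
  expect_error(generate_universe(10, pai_probabilities = rep(1 / 4, 4)),
               "16")
})

test_that("planted flag enrichment odds are recovered by the enrichment module", {
  specs <- list(
    is_development = list(base_rate = 0.15, odds = 4, condition = ~ di <= 0.25)
  )
  u <- generate_universe(12000, flag_specs = specs, seed = 31)
  g <- u$genes
  rate_low <- mean(g$is_development[g$di <= 0.25])
  rate_high <- mean(g$is_development[g$di > 0.25])
  odds <- (rate_low / (1 - rate_low)) / (rate_high / (1 - rate_high))
  expect_gt(odds, 2.5)
  expect_lt(odds, 6)
  res <- partition_2x2_test(g, ~ di <= 0.25, ~is_development)
  expect_lt(res$p.value, 0.001)
})

test_that("simulated codon pairs hit their target synonymous divergence and omega limits", {
  # omega = 0: all fixed differences synonymous, estimated ratio 0
  p0 <- simulate_codon_pair(400, omega = 0, target_ds = 0.05, seed = 17)
  expect_identical(p0$n_nonsyn_sub, 0L)
  est0 <- estimate_dnds(p0$seq_a, p0$seq_b)
  expect_equal(est0$ratio, 0)

  # target_ds = 0: identical pair
  pid <- simulate_codon_pair(100, omega = 1, target_ds = 0, seed = 17)
  expect_identical(pid$seq_a, pid$seq_b)

  # same seed, same pair
  expect_identical(
    simulate_codon_pair(200, 0.5, 0.05, seed = 3),
    simulate_codon_pair(200, 0.5, 0.05, seed = 3)
  )
  expect_error(simulate_codon_pair(100, omega = -1, target_ds = 0.1), "omega")
})

test_that("simulated sequences contain no internal stop codons", {
  p <- simulate_codon_pair(500, omega = 2, target_ds = 0.1, seed = 23)
  for (s in c(p$seq_a, p$seq_b)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(GC_TABLE[cods] == "*"))
  }
})

test_that("the study-like fixture plants the published set sizes and category counts", {
  fx <- generate_paperlike_fixture()
  g <- fx$genes
  expect_identical(nrow(g), 19504L)
  expect_identical(nrow(fx$sets$Receptors_80), 80L)
  expect_identical(nrow(fx$sets$allGPCR_420), 420L)

  inter <- intersect_sets(fx$sets$Receptors_80, fx$sets$allGPCR_420)
  expect_identical(nrow(inter), 67L)
  expect_identical(nrow(difference_sets(fx$sets$Receptors_80,
                                        fx$sets$allGPCR_420)), 13L)
  expect_identical(nrow(development_filter(
    g[g$gene_id %in% fx$sets$Receptors_80$gene_id, ]
  )), 23L)

  expect_identical(sum(g$pai == 1L), 6350L)
  expect_identical(sum(g$pai == 6L), 3203L)
  expect_identical(sum(g$pai == 7L), 2708L)
  expect_identical(sum(g$pai %in% c(7L, 8L)), 3443L)
  expect_identical(sum(g$di <= 0.25), 8718L)
  expect_identical(sum(g$di > 1), 1141L)

  in80 <- g$gene_id %in% fx$sets$Receptors_80$gene_id
  ingp <- g$gene_id %in% fx$sets$allGPCR_420$gene_id
  expect_identical(sum(g$pai[in80] == 6L), 37L)
  expect_identical(sum(g$pai[ingp] == 6L), 152L)
  expect_identical(sum(g$di[in80] <= 0.25), 45L)
  expect_identical(sum(g$di[ingp] <= 0.25), 174L)
  expect_identical(sum(g$is_development[in80] & g$di[in80] <= 0.25), 18L)
  expect_identical(sum(g$is_development[in80] & g$di[in80] > 0.25), 5L)

  # flags are internally consistent with the keyword filter
  dev_by_filter <- development_filter(g)$gene_id
  expect_setequal(dev_by_filter, g$gene_id[g$is_development])

  # fixture is deterministic
  expect_identical(fx$genes, generate_paperlike_fixture()$genes)
})
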