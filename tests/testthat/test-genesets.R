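make_universe <- function(n, overlap) {
  ids <- sprintf("u%03d", seq_len(n))
  list(
    ids = ids,
    a = gene_set(ids[1:80], "receptors"),
    b = gene_set(ids[c(1:overlap, 81:(80 + 420 - overlap))], "gpcr")
  )
}

test_that("set intersection and difference reproduce planted overlaps", {
  u <- make_universe(600, overlap = 67)
  inter <- intersect_sets(u$a, u$b)
  expect_identical(nrow(inter), 67L)
  diff <- difference_sets(u$a, u$b)
  expect_identical(nrow(diff), 13L)
  # algebra: |a| = |a & b| + |a \ b|; commutativity; idempotence
  expect_identical(nrow(u$a), nrow(inter) + nrow(diff))
  expect_setequal(intersect_sets(u$b, u$a)$gene_id, inter$gene_id)
  expect_setequal(intersect_sets(u$a, u$a)$gene_id, u$a$gene_id)
  expect_identical(nrow(difference_sets(u$a, u$a)), 0L)
  empty <- gene_set(character(), "empty")
  expect_setequal(difference_sets(u$a, empty)$gene_id, u$a$gene_id)
  expect_identical(nrow(intersect_sets(u$a, empty)), 0L)
})

test_that("development filter matches keywords case-insensitively as substrings", {
  u <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    go_terms = c(
      "positive regulation of neuron growth",
      "ion transport",
      "Embryonic Organ DEVELOPMENT;ion transport",
      "developmental pigmentation"
    )
  )
  hit <- development_filter(u)
  expect_setequal(hit$gene_id, c("g1", "g3", "g4")) # "developmental" matches too
  expect_error(development_filter(u, keywords = character()), "non-empty")

  # adding a non-matching term never changes membership
  u2 <- u
  u2$go_terms <- paste(u2$go_terms, "signal transduction", sep = ";")
  expect_setequal(development_filter(u2)$gene_id, hit$gene_id)
})

test_that("planted development annotations are recovered at the published count", {
  n_dev <- 23
  u <- tibble::tibble(
    gene_id = sprintf("r%02d", 1:80),
    go_terms = c(rep("tissue morphogenesis", n_dev), rep("ion transport", 80 - n_dev))
  )
  expect_identical(nrow(development_filter(u)), 23L)
})
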