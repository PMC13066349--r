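test_that("default ladder has 16 strictly ordered ranks with decreasing ages", {
  lad <- stratum_ladder()
  expect_identical(lad$rank, 1:16)
  expect_true(all(diff(lad$age_mya) < 0))
  expect_identical(lad$taxon[c(1, 6, 7, 16)],
                   c("Cellular organisms", "Vertebrata", "Euteleostomi",
                     "Homo sapiens"))
  expect_equal(lad$age_mya[c(1, 6, 16)], c(4100, 525, 0.35))
  expect_error(validate_ladder(lad[0, ]), "empty")
  bad <- lad
  bad$age_mya[3] <- 5000
  expect_error(validate_ladder(bad), "decrease")
})

test_that("PAI is the minimum rank among qualifying hits", {
  map <- tibble::tibble(species = c("spA", "spB"), rank = c(3L, 7L))
  hits <- tibble::tibble(
    gene_id = c("g1", "g1"),
    species = c("spA", "spB"),
    identity = c(0.62, 0.91)
  )
  expect_identical(assign_pai(hits, map)$pai, 3L)

  # sub-threshold hit is filtered; closed 50% bound
  sub <- tibble::tibble(gene_id = "g1", species = "spB", identity = 0.499)
  expect_identical(assign_pai(sub, map)$pai, 16L)
  at <- tibble::tibble(gene_id = "g1", species = "spB", identity = 0.5)
  expect_identical(assign_pai(at, map)$pai, 7L)

  # no hits at all -> focal rank
  none <- tibble::tibble(gene_id = character(), species = character(),
                         identity = numeric())
  expect_identical(assign_pai(none, map, gene_ids = "lonely")$pai, 16L)
})

test_that("assign_pai rejects unknown species, naming the label", {
  map <- tibble::tibble(species = "spA", rank = 3L)
  hits <- tibble::tibble(gene_id = "g1", species = "mystery_sp", identity = 0.9)
  expect_error(assign_pai(hits, map), "mystery_sp")
})

test_that("qualifying lower-rank hits can only lower the PAI; sub-threshold hits never change it", {
  map <- species_stratum_map()
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    hits <- tibble::tibble(
      gene_id = "g",
      species = sample(map$species[map$rank < 16], n),
      identity = runif(n)
    )
    base <- assign_pai(hits, map)$pai
    qual_rank <- sample(1:15, 1)
    plus <- dplyr::bind_rows(hits, tibble::tibble(
      gene_id = "g", species = map$species[map$rank == qual_rank][1],
      identity = runif(1, 0.5, 1)
    ))
    expect_lte(assign_pai(plus, map)$pai, base)

    noise_rank <- sample(1:15, 1)
    noisy <- dplyr::bind_rows(hits, tibble::tibble(
      gene_id = "g", species = map$species[map$rank == noise_rank][1],
      identity = runif(1, 0, 0.4999)
    ))
    expect_identical(assign_pai(noisy, map)$pai, base)
  }
})

test_that("age_distribution tabulates counts and exact percentages over all ranks", {
  d <- age_distribution(c(6, 6, 7))
  expect_identical(sum(d$n), 3L)
  expect_equal(sum(d$percent), 100, tolerance = 1e-9)
  expect_equal(d$percent[d$rank == 6], 200 / 3, tolerance = 1e-9)
  expect_equal(d$percent[d$rank == 7], 100 / 3, tolerance = 1e-9)
  expect_identical(nrow(d), 16L)

  expect_error(age_distribution(integer()), "empty input")
  expect_error(age_distribution(c(3, 17)), "ladder")

  many <- c(rep(6, 3203), rep(1, 19504 - 3203))
  big <- age_distribution(many)
  expect_equal(round(big$percent[big$rank == 6], 1), 16.4)
})
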