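#' Deterministic study-like gene universe fixture
#'
#' Builds, without any randomness, a synthetic universe of 19,504
#' protein-coding genes whose planted structure reproduces the marginal
#' counts of the published appetite-receptor analysis this package
#' emulates: a receptor set of 80 genes nesting a GPCR subset of 67 and a
#' non-GPCR remainder of 13 inside a 420-gene GPCR superfamily set;
#' 6,350 universe genes at PAI 1, 3,203 at PAI 6, 2,708 at PAI 7 and
#' 3,443 at PAI 7-or-8; 37 of the 80 (35 of the 67) at PAI 6 and 6 of
#' the 13 at PAI 7-or-8; 8,718 universe genes (44.7%), 45 of the 80,
#' 174 of the 420 and 38 of the 67 at DI <= 0.25; 1,141 universe genes
#' (5.85%) with DI > 1; and 23 development-annotated genes in the 80,
#' splitting 18 / 5 across the DI <= 0.25 boundary. Category counts are
#' planted exactly (not sampled) so downstream checks are deterministic.
#' Every gene id is synthetic (`g00001` ...); the fixture emulates the
#' shape of the study's supplementary tables, not their gene content.
#'
#' Ortholog hits are constructed so that [assign_pai()] recovers every
#' planted PAI (one hit of identity 0.8 at the planted rank; none for
#' focal-rank genes). Planted DI values stand in for divergence estimates
#' the original sequence data would provide.
#'
#' @return A list with elements `genes` (19,504-row tibble), `hits`,
#'   `sets` (named list with `Receptors_80` and `allGPCR_420` gene sets),
#'   `species_map`, `ladder`.
#' @export
generate_paperlike_fixture <- function() {
  ladder <- stratum_ladder()
  smap <- species_stratum_map(ladder)
  n_total <- 19504L
  ids <- sprintf("g%05d", seq_len(n_total))

  idx_appgpcr <- 1:67      # receptor genes that are GPCRs
  idx_appnot <- 68:80      # receptor genes outside the GPCR superfamily
  idx_gpcr_rest <- 81:433  # remaining GPCR-superfamily genes (353)
  idx_rest <- 434:n_total  # remaining protein-coding genes (19,071)

  pai <- integer(n_total)
  pai[idx_appgpcr] <- c(
    rep(6L, 35), rep(1L, 10), rep(2L, 2), rep(3L, 3), 4L,
    rep(7L, 8), rep(8L, 5), rep(9L, 3)
  )
  pai[idx_appnot] <- c(rep(6L, 2), rep(7L, 4), rep(8L, 2),
                       rep(1L, 2), 3L, rep(9L, 2))
  pai[idx_gpcr_rest] <- c(
    rep(6L, 117), rep(1L, 60), rep(2L, 30), rep(3L, 20), rep(7L, 50),
    rep(8L, 30), rep(9L, 20), rep(10L, 10), rep(11L, 6), rep(12L, 4),
    rep(13L, 3), rep(14L, 2), 15L
  )
  # remainder counts chosen so universe totals match the published
  # marginals (6350@1, 3203@6, 2708@7, 735@8 so that 3443 sit at 7-8,
  # 305 at 4-5) with a plausibly thinning tail elsewhere
  rest_counts <- c(
    6278, 2568, 1476, 149, 155, 3049, 2646, 698,
    625, 320, 274, 216, 187, 158, 139, 133
  )
  pai[idx_rest] <- rep(1:16, times = rest_counts)

  di <- numeric(n_total)
  di[idx_appgpcr] <- c(
    seq(0.01, 0.25, length.out = 38),        # DI <= 0.25
    seq(0.26, 0.99, length.out = 26),        # 0.25 < DI <= 1
    c(1.84, 1.21, 1.03)                      # the three high-DI receptors
  )
  di[idx_appnot] <- c(
    seq(0.02, 0.24, length.out = 7),
    seq(0.30, 0.90, length.out = 6)
  )
  di[idx_gpcr_rest] <- c(
    seq(0.005, 0.25, length.out = 136),
    seq(0.26, 1.00, length.out = 196),
    seq(1.02, 2.20, length.out = 21)
  )
  di[idx_rest] <- c(
    seq(0.003, 0.25, length.out = 8537),
    seq(0.2505, 1.00, length.out = 9417),
    seq(1.01, 3.00, length.out = 1117)
  )

  is_gpcr <- seq_len(n_total) %in% c(idx_appgpcr, idx_gpcr_rest)
  is_brain_specific <- seq_len(n_total) %in% c(1:12, 68:70) # 15 of the 80

  # development annotation: 18 of the 45 low-DI receptor genes and 5 of
  # the 35 others carry development/growth/morphogenesis GO terms
  dev_idx <- c(1:15, 68:70, 39:42, 75)
  is_development <- seq_len(n_total) %in% dev_idx
  dev_terms <- c(
    "positive regulation of neuron growth",
    "embryonic organ development",
    "tissue morphogenesis",
    "jaw development",
    "regulation of growth"
  )
  go_terms <- rep("", n_total)
  go_terms[dev_idx] <- paste(
    rep_len(dev_terms, length(dev_idx)),
    "signal transduction", sep = ";"
  )
  other80 <- setdiff(1:80, dev_idx)
  go_terms[other80] <- rep_len(
    c("ion transport", "G protein-coupled receptor signaling pathway"),
    length(other80)
  )

  ligand_type <- rep(NA_character_, n_total)
  ligand_type[1:80] <- c(
    rep("peptide", 45), rep("protein", 11), rep("lipid", 8),
    rep("aminergic", 7), "ion", rep("orphan", 8)
  )

  genes <- tibble::tibble(
    gene_id = ids,
    pai = pai,
    di = di,
    is_gpcr = is_gpcr,
    is_brain_specific = is_brain_specific,
    is_development = is_development,
    ligand_type = ligand_type,
    go_terms = go_terms
  )

  with_hit <- pai < 16L
  hits <- tibble::tibble(
    gene_id = ids[with_hit],
    species = smap$species[match(pai[with_hit], smap$rank)],
    identity = 0.8
  )

  sets <- list(
    Receptors_80 = gene_set(ids[1:80], "Receptors_80"),
    allGPCR_420 = gene_set(ids[c(idx_appgpcr, idx_gpcr_rest)], "allGPCR_420")
  )

  list(genes = genes, hits = hits, sets = sets,
       species_map = smap, ladder = ladder)
}
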