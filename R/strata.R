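#' The default 16-rank taxon ladder for the human lineage
#'
#' The ladder of taxonomic stages used to date gene origins on the lineage
#' from the root of the tree of life (cellular organisms) to modern humans.
#' A gene's phylostratigraphic age index (PAI) is the rank of the deepest
#' stage at which an ortholog is still detected: rank 1 means the gene
#' traces back to cellular organisms (oldest), rank 16 means it is found
#' only in the focal species (youngest). Approximate divergence ages are
#' in millions of years ago (Mya).
#'
#' @return A tibble with columns `rank` (integer 1..16), `taxon`
#'   (character) and `age_mya` (numeric, strictly decreasing with rank).
#' @seealso [assign_pai()], [species_stratum_map()]
#' @export
#' @examples
#' stratum_ladder()
stratum_ladder <- function() {
  tibble::tibble(
    rank = 1:16,
    taxon = c(
      "Cellular organisms", "Eukaryota", "Metazoa", "Chordata",
      "Craniata", "Vertebrata", "Euteleostomi", "Mammalia",
      "Eutheria", "Euarchontoglires", "Primates", "Haplorrhini",
      "Catarrhini", "Hominidae", "Homo", "Homo sapiens"
    ),
    age_mya = c(
      4100, 1850, 665, 541, 535, 525, 420, 225,
      160, 65, 55, 50, 44, 17, 2.8, 0.35
    )
  )
}

#' Validate a taxon ladder
#'
#' Checks the structural invariants of a stratum ladder: ranks are exactly
#' `1..nrow`, unique and increasing, and ages decrease strictly with rank.
#'
#' @param ladder a data frame with columns `rank`, `taxon`, `age_mya`.
#' @return `ladder`, invisibly, as a tibble.
#' @export
validate_ladder <- function(ladder) {
  if (is.null(ladder) || nrow(ladder) == 0) abort("Ladder is empty.")
  check_columns(ladder, c("rank", "taxon", "age_mya"), "Ladder")
  if (!identical(as.integer(ladder$rank), seq_len(nrow(ladder)))) {
    abort("Ladder ranks must be exactly 1..n, strictly increasing and unique.")
  }
  if (any(diff(ladder$age_mya) >= 0)) {
    abort("Ladder ages (age_mya) must strictly decrease with rank.")
  }
  invisible(tibble::as_tibble(ladder))
}

#' Default species-to-stratum map
#'
#' Maps ortholog subject species to the ladder rank of the stage at which
#' that species' lineage diverged from the focal (human) lineage. The
#' default is a synthetic convenience map with one representative species
#' per stage, emulating the assignment a sequence-similarity database
#' search would produce; real analyses should supply their own map.
#'
#' @param ladder a stratum ladder, used only to validate ranks.
#' @return A tibble with columns `species` and `rank`.
#' @export
species_stratum_map <- function(ladder = stratum_ladder()) {
  validate_ladder(ladder)
  map <- tibble::tibble(
    species = c(
      "Escherichia coli", "Saccharomyces cerevisiae",
      "Drosophila melanogaster", "Ciona intestinalis",
      "Eptatretus burgeri", "Petromyzon marinus", "Danio rerio",
      "Gallus gallus", "Monodelphis domestica", "Canis lupus familiaris",
      "Mus musculus", "Microcebus murinus", "Macaca mulatta",
      "Pongo abelii", "Pan troglodytes", "Homo sapiens"
    ),
    rank = 1:16
  )
  validate_species_map(map, ladder)
}

#' Validate a species-to-stratum map against a ladder
#'
#' @param map data frame with columns `species`, `rank`.
#' @param ladder stratum ladder the ranks must belong to.
#' @return the map as a tibble (invisibly usable).
#' @export
validate_species_map <- function(map, ladder = stratum_ladder()) {
  validate_ladder(ladder)
  check_columns(map, c("species", "rank"), "Species map")
  if (anyDuplicated(map$species)) abort("Species map contains duplicate species labels.")
  bad <- setdiff(map$rank, ladder$rank)
  if (length(bad) > 0) {
    abort(sprintf("Species map contains rank(s) not in the ladder: %s.",
                  paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(map)
}

#' Assign phylostratigraphic age indices from ortholog hits
#'
#' For each gene, the PAI is the minimum ladder rank among species in
#' which an ortholog with identity at or above `identity_threshold` was
#' found (the bound is closed: identity exactly equal to the threshold
#' qualifies). A gene with no qualifying hit in any non-focal species is
#' assigned the focal rank (16 by default): no detectable ortholog outside
#' the focal species means the gene is dated to the youngest stage.
#'
#' @param hits data frame of ortholog hits with columns `gene_id`,
#'   `species`, `identity` (fraction in \[0, 1\]).
#' @param species_map data frame mapping `species` to ladder `rank`.
#' @param ladder stratum ladder (defaults to [stratum_ladder()]).
#' @param identity_threshold minimum identity fraction for a hit to count;
#'   default 0.5 ("50% or more identical").
#' @param gene_ids optional character vector of gene ids that must appear
#'   in the result even if they have no hits (they receive the focal rank).
#' @return A tibble with columns `gene_id` and `pai` (integer rank).
#' @export
#' @examples
#' map <- tibble::tibble(species = c("spA", "spB"), rank = c(3L, 7L))
#' hits <- tibble::tibble(
#'   gene_id = c("g1", "g1"), species = c("spA", "spB"),
#'   identity = c(0.62, 0.91)
#' )
#' assign_pai(hits, map) # g1 -> 3
assign_pai <- function(hits, species_map, ladder = stratum_ladder(),
                       identity_threshold = 0.5, gene_ids = NULL) {
  validate_ladder(ladder)
  species_map <- validate_species_map(species_map, ladder)
  check_scalar_number(identity_threshold, "identity_threshold", 1e-12, 1)
  check_columns(hits, c("gene_id", "species", "identity"), "Hits table")
  if (nrow(hits) > 0) {
    if (!is.numeric(hits$identity) || any(is.na(hits$identity)) ||
        any(hits$identity < 0 | hits$identity > 1)) {
      abort("Hit identities must be numeric fractions in [0, 1].")
    }
    unknown <- setdiff(unique(hits$species), species_map$species)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown species label(s) in hits: %s.",
                    paste(unknown, collapse = ", ")))
    }
  }
  focal_rank <- max(ladder$rank)

  assigned <- hits |>
    dplyr::filter(.data$identity >= identity_threshold) |>
    dplyr::inner_join(species_map, by = "species") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      pai = if (dplyr::n() > 0) as.integer(min(.data$rank)) else NA_integer_,
      .groups = "drop"
    )

  all_ids <- unique(c(hits$gene_id, gene_ids))
  tibble::tibble(gene_id = all_ids) |>
    dplyr::left_join(assigned, by = "gene_id") |>
    dplyr::mutate(pai = dplyr::coalesce(.data$pai, as.integer(focal_rank)))
}

#' Distribution of PAI values over the taxon ladder
#'
#' Tabulates counts and percentages of genes per ladder rank. Every rank
#' of the ladder appears in the output, including ranks with zero genes,
#' so distributions for different sets are directly comparable.
#'
#' @param pai_values integer vector of PAI ranks (all within the ladder).
#' @param ladder stratum ladder.
#' @param set_name optional label stored in a `set` column (useful when
#'   binding distributions of several sets for plotting).
#' @return A tibble of class `pai_distribution` with columns `set`,
#'   `rank`, `taxon`, `n`, `percent`. Percentages are exact (they sum to
#'   100) and are not rounded.
#' @export
age_distribution <- function(pai_values, ladder = stratum_ladder(),
                             set_name = "genes") {
  validate_ladder(ladder)
  if (length(pai_values) == 0) abort("empty input: no PAI values to tabulate.")
  if (any(is.na(pai_values)) || !all(pai_values %in% ladder$rank)) {
    abort("All PAI values must be non-missing ranks present in the ladder.")
  }
  counts <- table(factor(pai_values, levels = ladder$rank))
  out <- ladder |>
    dplyr::select("rank", "taxon") |>
    dplyr::mutate(
      set = set_name,
      n = as.integer(counts),
      percent = 100 * .data$n / length(pai_values),
      .before = "rank"
    )
  class(out) <- c("pai_distribution", class(out))
  out
}
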