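#' Estimate pairwise dN/dS from a codon-aligned sequence pair
#'
#' Nei–Gojobori (1986) counting with Jukes–Cantor correction. Codon
#' columns containing a gap or a non-ACGT symbol in either sequence are
#' discarded before counting (the number discarded is reported). Site
#' totals are averaged over the two sequences; substitution counts are
#' pathway-averaged per differing column ([count_differences()]). The
#' per-site proportions are corrected for multiple hits by
#' `d = -(3/4) * log(1 - 4p/3)`; proportions at or above 0.75 are
#' saturated and raise an error. The ratio `dN/dS` is defined only when
#' `dS > 0`; otherwise it is `NA` (a pair with no synonymous divergence
#' carries no information about relative rates).
#'
#' @param seq_a,seq_b aligned coding sequences (character strings of equal
#'   length, a multiple of 3; alignment gaps as `-`).
#' @param gene_id,species optional labels carried into the result.
#' @return A one-row tibble of class `dnds_estimate` with columns
#'   `gene_id`, `species`, `n_codons`, `n_discarded`, `n_sites`,
#'   `s_sites`, `nd`, `sd`, `pn`, `ps`, `dn`, `ds`, `ratio`.
#' @export
#' @examples
#' estimate_dnds("TTTGCTAAA", "TTCGCTAAA")
estimate_dnds <- function(seq_a, seq_b, gene_id = NA_character_,
                          species = NA_character_) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L) {
    abort("`seq_a` and `seq_b` must be single character strings.")
  }
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("Aligned sequences must have equal length.")
  }
  if (nchar(seq_a) %% 3 != 0) {
    abort("Aligned sequence length must be a multiple of 3.")
  }
  cod_a <- codon_split(seq_a)
  cod_b <- codon_split(seq_b)

  clean <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b)
  n_discarded <- sum(!clean)
  cod_a <- cod_a[clean]
  cod_b <- cod_b[clean]
  if (length(cod_a) == 0L) {
    abort("zero usable columns: every codon column contains a gap or ambiguity.")
  }
  gc <- genetic_code()
  stops <- gc[cod_a] == "*" | gc[cod_b] == "*"
  if (any(stops)) {
    abort(sprintf("Internal stop codon at alignment column %d.", which(stops)[1]))
  }

  tab <- ng86_site_table()
  sa <- tab$s_sites[match(cod_a, tab$codon)]
  sb <- tab$s_sites[match(cod_b, tab$codon)]
  s_sites <- (sum(sa) + sum(sb)) / 2
  n_sites <- 3 * length(cod_a) - s_sites

  differing <- which(cod_a != cod_b)
  if (length(differing) > 0) {
    cd <- count_differences(cod_a[differing], cod_b[differing])
    nd <- sum(cd$nd)
    sd <- sum(cd$sd)
  } else {
    nd <- sd <- 0
  }

  pn <- nd / n_sites
  ps <- sd / s_sites
  if (pn >= 0.75 || ps >= 0.75) {
    abort("saturation: correction undefined (pN or pS >= 0.75).")
  }
  dn <- jc_correct(pn)
  ds <- jc_correct(ps)
  ratio <- if (ds > 0) dn / ds else NA_real_

  out <- tibble::tibble(
    gene_id = gene_id, species = species,
    n_codons = length(cod_a), n_discarded = n_discarded,
    n_sites = n_sites, s_sites = s_sites,
    nd = nd, sd = sd, pn = pn, ps = ps,
    dn = dn, ds = ds, ratio = ratio
  )
  class(out) <- c("dnds_estimate", class(out))
  out
}

codon_split <- function(x) {
  substring(x, seq(1, nchar(x), by = 3), seq(3, nchar(x), by = 3))
}

jc_correct <- function(p) {
  if (p == 0) return(0)
  -0.75 * log(1 - 4 * p / 3)
}

#' Estimate dN/dS for a table of aligned pairs
#'
#' Applies [estimate_dnds()] to each row of a manifest of codon-aligned
#' pairs, e.g. one human gene against its ortholog in each comparator
#' species.
#'
#' @param pairs data frame with columns `gene_id`, `species`, `seq_a`,
#'   `seq_b`.
#' @return A tibble with one `dnds_estimate` row per input pair.
#' @export
dnds_pairs <- function(pairs) {
  check_columns(pairs, c("gene_id", "species", "seq_a", "seq_b"), "Pairs table")
  purrr::pmap(
    pairs[, c("gene_id", "species", "seq_a", "seq_b")],
    function(gene_id, species, seq_a, seq_b) {
      estimate_dnds(seq_a, seq_b, gene_id = gene_id, species = species)
    }
  ) |>
    purrr::list_rbind()
}

#' Aggregate pairwise ratios into per-gene divergence indices
#'
#' The divergence index (DI) of a gene is the arithmetic mean of its
#' defined pairwise dN/dS ratios across comparator species. Pairs whose
#' ratio is undefined (dS = 0) are excluded from the mean; when every
#' pair is excluded the DI itself is undefined (`NA`) and the selection
#' class is `"undefined"`.
#'
#' @param pair_estimates data frame with columns `gene_id`, `species`,
#'   `ratio` (e.g. the output of [dnds_pairs()]).
#' @param neutrality_band numeric length-2 interval classified as
#'   consistent with neutrality; see [classify_selection()].
#' @return A tibble with columns `gene_id`, `di`, `n_used`,
#'   `selection_class`.
#' @export
#' @examples
#' est <- tibble::tibble(
#'   gene_id = "g1", species = c("s1", "s2", "s3"),
#'   ratio = c(0.4, NA, 0.2)
#' )
#' compute_di(est) # di = 0.3 from the 2 defined pairs
compute_di <- function(pair_estimates, neutrality_band = c(0.9, 1.1)) {
  check_columns(pair_estimates, c("gene_id", "species", "ratio"),
                "Pair estimates")
  dup <- pair_estimates |>
    dplyr::count(.data$gene_id, .data$species) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate species per gene: %s.",
                  paste(unique(dup$gene_id), collapse = ", ")))
  }
  pair_estimates |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_used = sum(!is.na(.data$ratio)),
      di = ifelse(.data$n_used > 0, mean(.data$ratio, na.rm = TRUE), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      selection_class = classify_selection(.data$di, neutrality_band)
    ) |>
    dplyr::select("gene_id", "di", "n_used", "selection_class")
}

#' Classify the mode of selection from a divergence index
#'
#' A DI well below 1 indicates stabilizing (purifying) selection, a DI
#' near 1 is consistent with neutral evolution, and a DI above 1 suggests
#' diversifying (driving) selection. "Near 1" is operationalized as a
#' configurable band, `[0.9, 1.1]` by default.
#'
#' @param di numeric vector of divergence indices (`NA` allowed).
#' @param neutrality_band numeric length-2 closed interval.
#' @return Character vector over `stabilizing`, `neutral`, `diversifying`,
#'   `undefined`.
#' @export
#' @examples
#' classify_selection(c(0.026, 1.0, 1.84, NA))
classify_selection <- function(di, neutrality_band = c(0.9, 1.1)) {
  if (length(neutrality_band) != 2L || neutrality_band[1] > neutrality_band[2]) {
    abort("`neutrality_band` must be an increasing length-2 interval.")
  }
  if (any(!is.na(di) & di < 0)) abort("DI values must be non-negative.")
  dplyr::case_when(
    is.na(di) ~ "undefined",
    di < neutrality_band[1] ~ "stabilizing",
    di > neutrality_band[2] ~ "diversifying",
    .default = "neutral"
  )
}
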