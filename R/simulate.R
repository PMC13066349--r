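# Synthetic-data generators: a seeded gene universe with planted PAI/DI
# structure and ortholog hit tables, and a codon-pair simulator evolving
# sequences under a chosen dN/dS ratio. These produce inputs with the
# statistical structure the analysis assumes, so every stage can be run
# and validated without external databases.

eval_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L) abort("`seed` must be a single integer.")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Default PAI sampling probabilities for a synthetic gene universe
#'
#' A 16-vector of per-rank probabilities anchored to the landmark
#' proportions of the human protein-coding distribution: about a third of
#' genes at rank 1 (cellular organisms), roughly 16% at rank 6
#' (Vertebrata) and 14% at rank 7 (Euteleostomi), very few at ranks 4-5,
#' and a thinning tail towards the focal species.
#'
#' @return Numeric vector of length 16 summing to 1.
#' @export
default_pai_probabilities <- function() {
  counts <- c(
    6350, 2600, 1500, 150, 155, 3203, 2708, 735,
    650, 330, 280, 220, 190, 160, 140, 133
  )
  counts / sum(counts)
}

#' Default DI mixture for a synthetic gene universe
#'
#' A single log-normal component with `meanlog = -1.2776` and
#' `sdlog = 0.816`, chosen so that the planted distribution puts 44.7% of
#' genes at DI <= 0.25 and 5.85% above 1 — the genome-wide proportions
#' the enrichment analysis assumes for its background.
#'
#' @return A tibble with columns `weight`, `distribution` (`"lognormal"`
#'   or `"point"`), `meanlog`, `sdlog`, `value`.
#' @export
default_di_mixture <- function() {
  tibble::tibble(
    weight = 1,
    distribution = "lognormal",
    meanlog = -1.2776,
    sdlog = 0.816,
    value = NA_real_
  )
}

sample_di_mixture <- function(n, mixture) {
  check_columns(mixture, c("weight", "distribution"), "DI mixture")
  if (abs(sum(mixture$weight) - 1) > 1e-9) abort("Mixture weights must sum to 1.")
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  out <- numeric(n)
  for (j in seq_len(nrow(mixture))) {
    idx <- comp == j
    if (!any(idx)) next
    out[idx] <- switch(mixture$distribution[j],
      lognormal = rlnorm(sum(idx), mixture$meanlog[j], mixture$sdlog[j]),
      point = rep(mixture$value[j], sum(idx)),
      abort(sprintf("Unknown mixture distribution: %s.", mixture$distribution[j]))
    )
  }
  out
}

#' Default annotation-flag specifications
#'
#' Each flag is drawn per gene with a base rate; when a conditioning
#' predicate is given, genes satisfying it have their odds of carrying
#' the flag multiplied by `odds`. Defaults: a GPCR flag at the genome-wide
#' prevalence of GPCR genes (~2.2%), a brain-specific expression flag at
#' ~1.9%, and a development-annotation flag at 15% base rate, enriched
#' 2-fold (odds) among genes under strong purifying selection
#' (DI <= 0.25).
#'
#' @return A named list of flag specifications (`base_rate`, `odds`,
#'   `condition`, a one-sided formula or `NULL`).
#' @export
default_flag_specs <- function() {
  list(
    is_gpcr = list(base_rate = 420 / 19504, odds = 1, condition = NULL),
    is_brain_specific = list(base_rate = 0.019, odds = 1, condition = NULL),
    is_development = list(base_rate = 0.15, odds = 2, condition = ~ di <= 0.25)
  )
}

#' Generate a synthetic gene universe with ortholog hit tables
#'
#' Draws per-gene PAI ranks, DI values and annotation flags from the
#' given specifications, and constructs ortholog hit tables so that
#' [assign_pai()] recovers the planted PAI of every gene exactly: each
#' gene with planted rank below the focal rank gets one qualifying hit
#' (identity >= 0.5) at a species of that rank, possibly extra qualifying
#' hits at shallower (higher) ranks, and possibly sub-threshold decoy
#' hits at deeper ranks, which must not affect the assignment.
#'
#' @param n_genes number of genes.
#' @param pai_probabilities length-16 probability vector over ranks
#'   (must sum to 1 within 1e-9).
#' @param di_mixture DI mixture specification ([default_di_mixture()]).
#' @param flag_specs named list of flag specifications
#'   ([default_flag_specs()]).
#' @param species_map,ladder taxon scaffolding.
#' @param seed integer seed; the output is reproducible under a fixed
#'   seed (R's default Mersenne-Twister generator).
#' @return A list with elements `genes` (tibble: `gene_id`, `pai`, `di`,
#'   one column per flag, `ligand_type`, `go_terms`), `hits` (tibble:
#'   `gene_id`, `species`, `identity`), `species_map`, `ladder`.
#' @export
generate_universe <- function(n_genes,
                              pai_probabilities = default_pai_probabilities(),
                              di_mixture = default_di_mixture(),
                              flag_specs = default_flag_specs(),
                              species_map = species_stratum_map(),
                              ladder = stratum_ladder(),
                              seed = NULL) {
  check_scalar_number(n_genes, "n_genes", lower = 1)
  validate_ladder(ladder)
  species_map <- validate_species_map(species_map, ladder)
  n_ranks <- nrow(ladder)
  if (length(pai_probabilities) != n_ranks ||
      any(pai_probabilities < 0) ||
      abs(sum(pai_probabilities) - 1) > 1e-9) {
    abort(sprintf(
      "`pai_probabilities` must be %d non-negative values summing to 1.",
      n_ranks
    ))
  }
  eval_with_seed(seed, {
    gene_id <- sprintf("sg%06d", seq_len(n_genes))
    pai <- sample.int(n_ranks, n_genes, replace = TRUE, prob = pai_probabilities)
    di <- sample_di_mixture(n_genes, di_mixture)

    genes <- tibble::tibble(gene_id = gene_id, pai = as.integer(pai), di = di)
    for (flag in names(flag_specs)) {
      spec <- flag_specs[[flag]]
      p <- rep(spec$base_rate, n_genes)
      if (!is.null(spec$condition)) {
        cond <- rlang::eval_tidy(rlang::f_rhs(spec$condition), data = genes)
        odds0 <- spec$base_rate / (1 - spec$base_rate)
        odds1 <- odds0 * spec$odds
        p[cond %in% TRUE] <- odds1 / (1 + odds1)
      }
      genes[[flag]] <- rbinom(n_genes, 1L, p) == 1L
    }
    genes$ligand_type <- NA_character_
    genes$go_terms <- ""

    hits <- build_planted_hits(genes$gene_id, pai, species_map, n_ranks)
    list(genes = genes, hits = hits, species_map = species_map, ladder = ladder)
  })
}

# one qualifying hit at the planted rank, optional extra qualifying hits
# at shallower ranks and sub-threshold decoys at deeper ranks (vectorized;
# requires the species map to cover every non-focal rank)
build_planted_hits <- function(gene_id, pai, species_map, focal_rank) {
  missing_ranks <- setdiff(seq_len(focal_rank - 1), species_map$rank)
  if (length(missing_ranks) > 0) {
    abort(sprintf("Species map must cover every non-focal rank; missing: %s.",
                  paste(missing_ranks, collapse = ", ")))
  }
  species_of <- setNames(as.character(species_map$species), species_map$rank)
  n <- length(gene_id)

  has_main <- pai < focal_rank
  main <- tibble::tibble(
    gene_id = gene_id[has_main],
    rank = pai[has_main],
    identity = runif(sum(has_main), 0.5, 1)
  )

  # extra qualifying hit at a uniformly drawn shallower rank (never
  # changes the minimum qualifying rank)
  can_extra <- pai <= focal_rank - 2
  take_extra <- can_extra & runif(n) < 0.5
  extra <- tibble::tibble(
    gene_id = gene_id[take_extra],
    rank = pai[take_extra] + 1L +
      floor(runif(sum(take_extra)) * (focal_rank - 1 - pai[take_extra])),
    identity = runif(sum(take_extra), 0.5, 1)
  )

  # sub-threshold decoy at a deeper rank (filtered out by the threshold)
  can_decoy <- pai >= 2
  take_decoy <- can_decoy & runif(n) < 0.3
  decoy <- tibble::tibble(
    gene_id = gene_id[take_decoy],
    rank = 1L + floor(runif(sum(take_decoy)) * (pai[take_decoy] - 1)),
    identity = runif(sum(take_decoy), 0.05, 0.4999)
  )

  dplyr::bind_rows(main, extra, decoy) |>
    dplyr::mutate(species = unname(species_of[as.character(.data$rank)])) |>
    dplyr::arrange(.data$gene_id, .data$rank) |>
    dplyr::select("gene_id", "species", "identity")
}

#' Simulate a codon-aligned pair under a chosen dN/dS ratio
#'
#' Draws an ancestral sequence uniformly over sense codons and evolves a
#' copy by repeated single-nucleotide proposals until the realized
#' synonymous divergence (synonymous substitutions per synonymous site)
#' reaches `target_ds`. Proposals creating stop codons are rejected;
#' synonymous proposals are accepted with probability `min(1, 1/omega)`
#' and nonsynonymous proposals with probability `min(1, omega)`, so the
#' relative fixation rate of nonsynonymous to synonymous change is
#' `omega`. With `omega = 0` all fixed differences are synonymous.
#'
#' Transitions can be favoured over transversions via `ts_tv_ratio`; the
#' default of 1 matches the assumptions of the counting estimator, which
#' applies no transition-bias correction.
#'
#' @param n_codons sequence length in codons.
#' @param omega target dN/dS ratio (>= 0).
#' @param target_ds target synonymous divergence per synonymous site
#'   (>= 0; 0 returns an identical pair).
#' @param ts_tv_ratio proposal weight of the transition relative to each
#'   transversion at a position.
#' @param seed integer seed for reproducibility.
#' @return A one-row tibble with columns `seq_a` (ancestor), `seq_b`
#'   (derived), `n_codons`, `omega`, `target_ds`, `ts_tv_ratio`,
#'   `n_syn_sub`, `n_nonsyn_sub`.
#' @export
#' @examples
#' simulate_codon_pair(300, omega = 1, target_ds = 0.05, seed = 1)
simulate_codon_pair <- function(n_codons, omega, target_ds,
                                ts_tv_ratio = 1, seed = NULL) {
  check_scalar_number(n_codons, "n_codons", lower = 1)
  check_scalar_number(omega, "omega", lower = 0)
  check_scalar_number(target_ds, "target_ds", lower = 0)
  check_scalar_number(ts_tv_ratio, "ts_tv_ratio", lower = 1e-12)
  gc <- genetic_code()
  transition <- c(A = "G", G = "A", C = "T", T = "C")

  eval_with_seed(seed, {
    codons <- sense_codons()
    anc <- codons[sample.int(length(codons), n_codons, replace = TRUE)]
    tab <- ng86_site_table()
    s_sites <- sum(tab$s_sites[match(anc, tab$codon)])
    target_syn <- round(target_ds * s_sites)

    cur <- anc
    n_syn <- 0L
    n_nonsyn <- 0L
    acc_syn <- min(1, if (omega > 0) 1 / omega else 1)
    acc_nonsyn <- min(1, omega)
    while (n_syn < target_syn) {
      ci <- sample.int(n_codons, 1)
      pos <- sample.int(3, 1)
      cod <- cur[ci]
      base <- substr(cod, pos, pos)
      alts <- setdiff(BASES, base)
      w <- ifelse(alts == transition[[base]], ts_tv_ratio, 1)
      nb <- sample(alts, 1, prob = w)
      new_cod <- cod
      substr(new_cod, pos, pos) <- nb
      if (gc[[new_cod]] == "*") next
      syn <- gc[[new_cod]] == gc[[cod]]
      acc <- if (syn) acc_syn else acc_nonsyn
      if (acc < 1 && runif(1) > acc) next
      cur[ci] <- new_cod
      if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
    }
    tibble::tibble(
      seq_a = paste(anc, collapse = ""),
      seq_b = paste(cur, collapse = ""),
      n_codons = as.integer(n_codons),
      omega = omega, target_ds = target_ds, ts_tv_ratio = ts_tv_ratio,
      n_syn_sub = n_syn, n_nonsyn_sub = n_nonsyn
    )
  })
}
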