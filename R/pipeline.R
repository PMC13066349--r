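#' Pipeline configuration
#'
#' Collects the tunable parameters of the analysis in one place.
#'
#' @param identity_threshold minimum ortholog identity for PAI assignment
#'   (fraction; default 0.5, the closed "50% or more" bound).
#' @param pai_focal_ranks ladder rank(s) defining the age category tested
#'   for the focal and family sets (default 6, the modal vertebrate-stage
#'   rank).
#' @param pai_complement_ranks rank(s) tested for the complement
#'   (focal-minus-family) set (default 7 and 8).
#' @param di_cut inclusive DI threshold separating strongly constrained
#'   genes (default 0.25).
#' @param neutrality_band DI interval classified as neutral (default
#'   \[0.9, 1.1\]).
#' @param alpha_tiers significance thresholds reported as tiers.
#' @param comparator_species species used in pairwise dN/dS comparisons;
#'   defaults to four hominids.
#' @param development_keywords keywords for the GO-term filter.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(identity_threshold = 0.5,
                            pai_focal_ranks = 6L,
                            pai_complement_ranks = c(7L, 8L),
                            di_cut = 0.25,
                            neutrality_band = c(0.9, 1.1),
                            alpha_tiers = c(0.05, 0.01, 0.001),
                            comparator_species = c(
                              "Pan troglodytes", "Pan paniscus",
                              "Gorilla gorilla gorilla", "Pongo abelii"
                            ),
                            development_keywords = c(
                              "development", "growth", "morphogenesis"
                            )) {
  check_scalar_number(identity_threshold, "identity_threshold", 1e-12, 1)
  check_scalar_number(di_cut, "di_cut", lower = 1e-12)
  if (length(neutrality_band) != 2L || neutrality_band[1] > neutrality_band[2]) {
    abort("`neutrality_band` must be an increasing length-2 interval.")
  }
  if (is.unsorted(rev(sort(alpha_tiers)))) alpha_tiers <- sort(alpha_tiers, decreasing = TRUE)
  structure(
    list(
      identity_threshold = identity_threshold,
      pai_focal_ranks = as.integer(pai_focal_ranks),
      pai_complement_ranks = as.integer(pai_complement_ranks),
      di_cut = di_cut,
      neutrality_band = neutrality_band,
      alpha_tiers = alpha_tiers,
      comparator_species = comparator_species,
      development_keywords = development_keywords
    ),
    class = "pipeline_config"
  )
}

#' Run the full evolutionary-characterization pipeline
#'
#' Executes the analysis end to end on an input bundle: (1) PAI
#' assignment from ortholog hits; (2) DI, either computed from
#' codon-aligned pairs when `data$alignments` is supplied or taken from a
#' precomputed `di` column of the universe; (3) construction of the
#' derived sets (focal-within-family intersection, focal-minus-family
#' difference, development-filtered focal subset); (4) PAI and DI
#' distributions per set; (5) enrichment tests of each set against its
#' background, and a 2x2 test of development annotation against the DI
#' threshold within the focal set. Every filtering decision (genes
#' without hits, pairs dropped for dS = 0, discarded alignment columns,
#' genes excluded for missing values) is recorded in the report log.
#'
#' @param data list with elements `genes` (universe tibble with
#'   `gene_id`, optionally `pai`, `di`, flags, `go_terms`), `hits`
#'   (ortholog hit table, optional if `genes$pai` is present), `sets`
#'   (named list with elements `focal`-like and `family`-like gene sets;
#'   the first set is treated as focal, the second as the enclosing
#'   family), `species_map`, `ladder`, and optionally `alignments`
#'   (pair manifest for [dnds_pairs()]).
#' @param config a [pipeline_config()].
#' @return A list of class `genevol_report` with elements `genes`,
#'   `sets`, `pai_distributions`, `di_shares`, `enrichment`, `dev_2x2`,
#'   `config`, `log`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created by pipeline_config().")
  }
  if (is.null(data$genes) || nrow(data$genes) == 0) {
    abort("empty input: the gene universe is empty (stage: universe).")
  }
  check_columns(data$genes, "gene_id", "Universe")
  if (anyDuplicated(data$genes$gene_id)) {
    abort("Universe contains duplicate gene ids.")
  }
  ladder <- data$ladder %||% stratum_ladder()
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  genes <- tibble::as_tibble(data$genes)

  # --- stage 1: phylostratigraphic ages ---------------------------------
  if (!is.null(data$hits)) {
    if (is.null(data$species_map)) {
      abort("Missing input: `species_map` is required (stage: pai).")
    }
    pai_tbl <- assign_pai(
      data$hits, data$species_map, ladder,
      identity_threshold = config$identity_threshold,
      gene_ids = genes$gene_id
    )
    genes$pai <- pai_tbl$pai[match(genes$gene_id, pai_tbl$gene_id)]
    no_hit <- sum(!genes$gene_id %in% unique(data$hits$gene_id))
    note("pai: assigned from hits at threshold %g; %d gene(s) without hits set to focal rank.",
         config$identity_threshold, no_hit)
  } else if (!"pai" %in% names(genes)) {
    abort("Missing input: neither hits nor a precomputed `pai` column (stage: pai).")
  } else {
    note("pai: using precomputed `pai` column.")
  }

  # --- stage 2: divergence indices --------------------------------------
  if (!is.null(data$alignments)) {
    est <- dnds_pairs(data$alignments)
    n_undef <- sum(is.na(est$ratio))
    if (n_undef > 0) note("di: %d pair(s) excluded from DI means (dS = 0).", n_undef)
    n_disc <- sum(est$n_discarded)
    if (n_disc > 0) note("di: %d gapped/ambiguous codon column(s) discarded.", n_disc)
    di_tbl <- compute_di(est, config$neutrality_band)
    genes$di <- di_tbl$di[match(genes$gene_id, di_tbl$gene_id)]
    genes$selection_class <- di_tbl$selection_class[match(genes$gene_id, di_tbl$gene_id)]
    note("di: computed from %d alignment pair(s) for %d gene(s).",
         nrow(est), nrow(di_tbl))
  } else if ("di" %in% names(genes)) {
    genes$selection_class <- classify_selection(genes$di, config$neutrality_band)
    note("di: using precomputed `di` column.")
  } else {
    genes$di <- NA_real_
    genes$selection_class <- "undefined"
    note("di: no alignments and no `di` column; DI analyses will be skipped.")
  }

  # --- stage 3: set constructions ---------------------------------------
  if (length(data$sets) < 2) {
    abort("Missing input: `sets` must name a focal and a family set (stage: sets).")
  }
  focal <- data$sets[[1]]
  family <- data$sets[[2]]
  universe_set <- gene_set(genes$gene_id, "universe")
  inter <- intersect_sets(focal, family)
  compl <- difference_sets(focal, family)
  focal_genes <- genes[genes$gene_id %in% focal$gene_id, ]
  devel <- development_filter(focal_genes, config$development_keywords,
                              name = paste0(set_label(focal), "_development"))
  sets <- list(universe = universe_set, focal = focal, family = family,
               intersection = inter, complement = compl,
               development = devel)
  note("sets: sizes universe=%d, %s=%d, %s=%d, %s=%d, %s=%d, %s=%d.",
       nrow(universe_set),
       set_label(focal), nrow(focal), set_label(family), nrow(family),
       set_label(inter), nrow(inter), set_label(compl), nrow(compl),
       set_label(devel), nrow(devel))

  # --- stage 4: distributions -------------------------------------------
  dist_of <- function(s) {
    ids <- s$gene_id
    age_distribution(genes$pai[match(ids, genes$gene_id)], ladder,
                     set_name = set_label(s))
  }
  pai_distributions <- dplyr::bind_rows(lapply(
    sets[c("universe", "focal", "family", "intersection", "complement")],
    dist_of
  ))
  class(pai_distributions) <- c("pai_distribution", class(tibble::tibble()))

  has_di <- any(!is.na(genes$di))
  di_shares <- NULL
  dev_2x2 <- NULL
  if (!has_di) {
    warn("All DI values are missing; DI distributions and enrichment skipped.")
    note("di: all values missing; DI analyses skipped.")
  } else {
    share_of <- function(s) {
      v <- genes$di[match(s$gene_id, genes$gene_id)]
      dropped <- sum(is.na(v))
      if (dropped > 0) note("di share: %d gene(s) with missing DI dropped from %s.",
                            dropped, set_label(s))
      dplyr::mutate(threshold_share(v[!is.na(v)], config$di_cut),
                    set = set_label(s), .before = 1)
    }
    di_shares <- dplyr::bind_rows(lapply(
      sets[c("universe", "focal", "family", "intersection")], share_of
    ))
  }

  # --- stage 5: enrichment ----------------------------------------------
  ranks_label <- function(r) {
    if (length(r) == 1) paste0("PAI = ", r)
    else paste0("PAI in {", paste(r, collapse = ","), "}")
  }
  fr <- config$pai_focal_ranks
  cr <- config$pai_complement_ranks
  cut <- config$di_cut
  pai_cat <- function(r) rlang::new_formula(NULL, rlang::expr(pai %in% !!r))
  di_cat <- rlang::new_formula(NULL, rlang::expr(di <= !!cut))
  comparisons <- list(
    list(set = focal, background = universe_set,
         category = pai_cat(fr), label = ranks_label(fr)),
    list(set = family, background = universe_set,
         category = pai_cat(fr), label = ranks_label(fr)),
    list(set = inter, background = family,
         category = pai_cat(fr), label = ranks_label(fr)),
    list(set = compl, background = universe_set,
         category = pai_cat(cr), label = ranks_label(cr))
  )
  if (has_di) {
    comparisons <- c(comparisons, list(
      list(set = focal, background = universe_set,
           category = di_cat, label = paste0("DI <= ", cut)),
      list(set = inter, background = family,
           category = di_cat, label = paste0("DI <= ", cut))
    ))
  }
  enrichment <- dplyr::bind_rows(lapply(comparisons, function(cmp) {
    enrich(genes, cmp$set, cmp$background, cmp$category,
           category_label = cmp$label, alpha_tiers = config$alpha_tiers)
  }))
  class(enrichment) <- c("enrichment_result", class(tibble::tibble()))

  if (has_di) {
    in_dev <- focal_genes$gene_id %in% devel$gene_id
    fg <- dplyr::mutate(focal_genes, .in_dev = in_dev)
    dev_2x2 <- partition_2x2_test(fg, di_cat, ~ .in_dev)
  }

  structure(
    list(
      genes = genes, sets = sets,
      pai_distributions = pai_distributions,
      di_shares = di_shares,
      enrichment = enrichment,
      dev_2x2 = dev_2x2,
      config = config,
      log = log
    ),
    class = "genevol_report"
  )
}

#' @export
print.genevol_report <- function(x, ...) {
  cat(sprintf("genevol report: %d genes, %d sets\n",
              nrow(x$genes), length(x$sets)))
  cat("Enrichment tests:\n")
  print(dplyr::mutate(
    tibble::as_tibble(x$enrichment)[, c("set", "background", "category",
                                        "observed", "expected", "n", "p", "tier")],
    expected = round_half_up(.data$expected, 2)
  ))
  if (!is.null(x$dev_2x2)) {
    cat("\nDevelopment x DI-threshold partition:\n")
    print(x$dev_2x2)
  }
  invisible(x)
}
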