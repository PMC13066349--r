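#' Expected count of category members under a background distribution
#'
#' The number of genes expected to fall in a category within a set of
#' size `n`, if the set followed the background set's distribution:
#' `n * background_in / background_total`. Reports keep full precision
#' internally and print at two decimals ([round_half_up()]).
#'
#' @param n size of the analyzed set.
#' @param background_in number of background genes in the category.
#' @param background_total background set size (must be positive).
#' @return Expected count (full precision).
#' @export
#' @examples
#' expected_count(80, 3203, 19504) # 13.1378...
expected_count <- function(n, background_in, background_total) {
  check_scalar_number(n, "n", lower = 0)
  check_scalar_number(background_total, "background_total", lower = 1e-12)
  check_scalar_number(background_in, "background_in",
                      lower = 0, upper = background_total)
  n * background_in / background_total
}

#' Two-cell chi-square goodness-of-fit test
#'
#' Tests whether the observed number of genes in a category differs from
#' the expected number, by partitioning the set into in-category and
#' out-of-category cells:
#' `chi2 = (obs - exp)^2 / exp + ((n - obs) - (n - exp))^2 / (n - exp)`,
#' with 1 degree of freedom and no continuity correction.
#'
#' @param observed observed in-category count (0..n).
#' @param expected expected in-category count, strictly between 0 and n.
#' @param n set size.
#' @param alpha_tiers significance thresholds used for the tier label.
#' @return An object of class `gof_test`: a list with elements
#'   `statistic`, `df`, `p.value`, `observed`, `expected`, `n`, `tier`
#'   and `direction` (`enriched`/`depleted` when significant at the
#'   loosest tier, `none` otherwise). Supports [tidy()] and [glance()].
#' @export
#' @examples
#' gof_chi2(37, 13.14, 80)
gof_chi2 <- function(observed, expected, n,
                     alpha_tiers = c(0.05, 0.01, 0.001)) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(observed, "observed", lower = 0, upper = n)
  check_scalar_number(expected, "expected")
  if (expected <= 0 || expected >= n) {
    abort("`expected` must lie strictly between 0 and n.")
  }
  chi2 <- (observed - expected)^2 / expected +
    ((n - observed) - (n - expected))^2 / (n - expected)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  tier <- tier_label(p, alpha_tiers)
  direction <- if (p < max(alpha_tiers)) {
    if (observed > expected) "enriched" else "depleted"
  } else {
    "none"
  }
  structure(
    list(
      statistic = chi2, df = 1L, p.value = p,
      observed = observed, expected = expected, n = n,
      tier = tier, direction = direction
    ),
    class = "gof_test"
  )
}

#' @export
print.gof_test <- function(x, ...) {
  cat("Two-cell chi-square goodness of fit (df = 1)\n")
  cat(sprintf("  observed = %g, expected = %.2f, n = %g\n",
              x$observed, round_half_up(x$expected, 2), x$n))
  cat(sprintf("  X-squared = %.4g, p = %.4g (%s), %s\n",
              x$statistic, x$p.value, x$tier, x$direction))
  invisible(x)
}

#' Enrichment of a gene set in a category, against a background set
#'
#' Counts how many genes of `set` satisfy a category predicate, derives
#' the expected count from the predicate's prevalence in `background`,
#' and tests the difference with [gof_chi2()]. Genes for which the
#' predicate evaluates to `NA` (e.g. missing DI) are excluded from both
#' numerator and denominator; the exclusions are reported.
#'
#' @param universe data frame of gene records (must contain `gene_id`
#'   plus the columns the predicate uses).
#' @param set,background gene sets ([gene_set()]); members must belong to
#'   the universe.
#' @param category one-sided formula evaluated in the universe, e.g.
#'   `~ pai == 6` or `~ di <= 0.25`.
#' @param category_label label stored in the result; defaults to the
#'   deparsed formula.
#' @param alpha_tiers significance thresholds for the tier label.
#' @return A one-row tibble of class `enrichment_result` with columns
#'   `set`, `background`, `category`, `observed`, `expected`, `n`,
#'   `background_in`, `background_total`, `chi2`, `df`, `p`, `tier`,
#'   `direction`, `n_missing_set`, `n_missing_background`.
#' @export
enrich <- function(universe, set, background, category,
                   category_label = NULL,
                   alpha_tiers = c(0.05, 0.01, 0.001)) {
  check_columns(universe, "gene_id", "Universe")
  if (!rlang::is_formula(category)) {
    abort("`category` must be a one-sided formula, e.g. `~ pai == 6`.")
  }
  category_label <- category_label %||%
    rlang::as_label(rlang::f_rhs(category))
  in_cat <- rlang::eval_tidy(rlang::f_rhs(category), data = universe)
  if (!is.logical(in_cat) || length(in_cat) != nrow(universe)) {
    abort("`category` must evaluate to one logical per universe gene.")
  }

  tally <- function(ids) {
    idx <- match(ids, universe$gene_id)
    if (anyNA(idx)) abort("Gene set contains ids absent from the universe.")
    v <- in_cat[idx]
    c(inside = sum(v, na.rm = TRUE), total = sum(!is.na(v)),
      missing = sum(is.na(v)))
  }
  s <- tally(set$gene_id)
  b <- tally(background$gene_id)
  if (b[["total"]] == 0) abort("Background has no genes with a defined category value.")

  expected <- expected_count(s[["total"]], b[["inside"]], b[["total"]])
  test <- gof_chi2(s[["inside"]], expected, s[["total"]],
                   alpha_tiers = alpha_tiers)

  out <- tibble::tibble(
    set = set_label(set),
    background = set_label(background),
    category = category_label,
    observed = as.integer(s[["inside"]]),
    expected = expected,
    n = as.integer(s[["total"]]),
    background_in = as.integer(b[["inside"]]),
    background_total = as.integer(b[["total"]]),
    chi2 = test$statistic,
    df = 1L,
    p = test$p.value,
    tier = test$tier,
    direction = test$direction,
    n_missing_set = as.integer(s[["missing"]]),
    n_missing_background = as.integer(b[["missing"]])
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Chi-square test of independence on a 2x2 gene partition
#'
#' Cross-classifies genes by two predicates (e.g. DI <= 0.25 versus
#' association with development), computes expected cell counts from the
#' margins under independence, and sums the 4-cell chi-square with 1 df
#' and no continuity correction. Genes with `NA` under either predicate
#' are excluded (and counted).
#'
#' @param genes data frame of gene records.
#' @param row_predicate,col_predicate one-sided formulas evaluated in
#'   `genes`.
#' @return An object of class `indep_test`: list with `observed` and
#'   `expected` 2x2 matrices (rows: predicate TRUE/FALSE), `statistic`,
#'   `df`, `p.value`, `n`, `n_missing`, `tier`. Supports [tidy()] /
#'   [glance()].
#' @export
partition_2x2_test <- function(genes, row_predicate, col_predicate) {
  rv <- rlang::eval_tidy(rlang::f_rhs(row_predicate), data = genes)
  cv <- rlang::eval_tidy(rlang::f_rhs(col_predicate), data = genes)
  keep <- !is.na(rv) & !is.na(cv)
  n_missing <- sum(!keep)
  rv <- rv[keep]
  cv <- cv[keep]
  obs <- rbind(
    c(sum(rv & cv), sum(rv & !cv)),
    c(sum(!rv & cv), sum(!rv & !cv))
  )
  dimnames(obs) <- list(
    c("row_true", "row_false"),
    c("col_true", "col_false")
  )
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    abort("Zero margin: both predicates must split the genes.")
  }
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi2 <- sum((obs - expected)^2 / expected)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(
    list(
      observed = obs, expected = expected,
      statistic = chi2, df = 1L, p.value = p,
      n = sum(obs), n_missing = n_missing,
      tier = tier_label(p)
    ),
    class = "indep_test"
  )
}

#' @export
print.indep_test <- function(x, ...) {
  cat("2x2 chi-square test of independence (df = 1, no correction)\n")
  cat("Observed:\n")
  print(x$observed)
  cat("Expected:\n")
  print(round_half_up(x$expected, 2))
  cat(sprintf("X-squared = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p.value, x$tier))
  invisible(x)
}

#' Share of values at or below a threshold
#'
#' The threshold is inclusive: values exactly equal to `cut` are counted
#' in. The percentage is rounded half-away-from-zero at one decimal,
#' matching the reporting convention (45 of 80 -> 56.3).
#'
#' @param di_values numeric vector (no missing values).
#' @param cut positive threshold; default 0.25.
#' @return A tibble with columns `cut`, `count`, `total`, `percent`.
#' @export
#' @examples
#' threshold_share(c(rep(0.1, 45), rep(0.5, 35)), 0.25)
threshold_share <- function(di_values, cut = 0.25) {
  if (length(di_values) == 0) abort("empty input: no values.")
  if (any(is.na(di_values))) abort("Missing values are not allowed here; drop them first.")
  check_scalar_number(cut, "cut", lower = 1e-12)
  count <- sum(di_values <= cut)
  tibble::tibble(
    cut = cut,
    count = as.integer(count),
    total = length(di_values),
    percent = round_half_up(100 * count / length(di_values), 1)
  )
}

#' Binned distribution of divergence-index values
#'
#' Fixed-width bins from 0, right-closed (a value equal to a bin's upper
#' edge falls in that bin, consistent with the inclusive thresholds used
#' elsewhere).
#'
#' @param di_values numeric vector (no missing values).
#' @param bin_width positive bin width; default 0.05.
#' @param set_name optional label for plotting.
#' @return A tibble of class `di_distribution` with columns `set`,
#'   `bin_start`, `bin_end`, `n`, `percent`.
#' @export
di_histogram <- function(di_values, bin_width = 0.05, set_name = "genes") {
  if (length(di_values) == 0) abort("empty input: no values.")
  if (any(is.na(di_values))) abort("Missing values are not allowed here; drop them first.")
  check_scalar_number(bin_width, "bin_width", lower = 1e-12)
  n_bins <- max(1, ceiling(max(di_values) / bin_width - 1e-9))
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  idx <- pmax(1L, ceiling(di_values / bin_width - 1e-9))
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble::tibble(
    set = set_name,
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    n = counts,
    percent = 100 * counts / length(di_values)
  )
  class(out) <- c("di_distribution", class(out))
  out
}

#' Exact binomial upper-tail probability
#'
#' Probability of observing `k` or more successes in `n` trials with
#' per-trial probability `p`: a convenience for asking how surprising a
#' cluster of genes sharing a character is under independent sampling.
#' Note the appropriate null proportion is an analysis choice.
#'
#' @param k number of successes (0..n).
#' @param n number of trials.
#' @param p success probability in (0, 1).
#' @return `P(X >= k)` for `X ~ Binomial(n, p)`.
#' @export
#' @examples
#' binomial_tail(8, 11, 0.1642)
binomial_tail <- function(k, n, p) {
  check_scalar_number(n, "n", lower = 0)
  check_scalar_number(k, "k", lower = 0, upper = n)
  check_scalar_number(p, "p", lower = 1e-12, upper = 1 - 1e-12)
  pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}
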