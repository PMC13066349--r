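# broom-style tidiers for the test objects and the report bundle

#' @export
tidy.gof_test <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    expected = x$expected,
    n = x$n,
    statistic = x$statistic,
    df = x$df,
    p.value = x$p.value,
    tier = x$tier,
    direction = x$direction
  )
}

#' @export
glance.gof_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' @export
tidy.indep_test <- function(x, ...) {
  cells <- expand.grid(
    row = rownames(x$observed), col = colnames(x$observed),
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    row = cells$row, col = cells$col,
    observed = as.vector(x$observed),
    expected = as.vector(x$expected)
  )
}

#' @export
glance.indep_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    n = x$n, n_missing = x$n_missing, tier = x$tier
  )
}

#' @export
tidy.genevol_report <- function(x, ...) {
  tibble::as_tibble(x$enrichment)
}

#' @export
glance.genevol_report <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_sets = length(x$sets),
    n_tests = nrow(x$enrichment) + as.integer(!is.null(x$dev_2x2)),
    n_significant = sum(x$enrichment$p < max(x$config$alpha_tiers)) +
      as.integer(!is.null(x$dev_2x2) &&
                   x$dev_2x2$p.value < max(x$config$alpha_tiers))
  )
}
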