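#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching how values
#' are conventionally printed in reports (e.g. 56.25% -> 56.3%). Base R's
#' `round()` rounds ties to even (56.25 -> 56.2), which does not match
#' the reporting convention used throughout this package.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(56.25, 1) # 56.3
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared argument checks -------------------------------------------------

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# significance tier label: smallest alpha in `tiers` that p falls under
tier_label <- function(p, tiers = c(0.05, 0.01, 0.001)) {
  tiers <- sort(tiers, decreasing = TRUE)
  out <- rep("ns", length(p))
  for (a in tiers) out[!is.na(p) & p < a] <- paste0("p<", format(a, scientific = FALSE))
  out[is.na(p)] <- NA_character_
  out
}
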