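#' Construct a gene set
#'
#' A gene set is represented as a tidy tibble with one row per member
#' gene, carrying the set name alongside, so sets compose naturally with
#' dplyr verbs.
#'
#' @param members character vector of gene ids (deduplicated).
#' @param name set name.
#' @return A tibble of class `gene_set` with columns `set`, `gene_id`.
#' @export
gene_set <- function(members, name = "set") {
  members <- unique(as.character(members))
  out <- tibble::tibble(set = rep(name, length(members)), gene_id = members)
  class(out) <- c("gene_set", class(out))
  out
}

#' Intersection of two gene sets
#'
#' @param a,b gene sets (see [gene_set()]).
#' @param name name of the resulting set; default joins the input names.
#' @return A `gene_set` containing genes present in both inputs.
#' @export
intersect_sets <- function(a, b, name = NULL) {
  check_columns(a, "gene_id", "Gene set `a`")
  check_columns(b, "gene_id", "Gene set `b`")
  name <- name %||% paste0(set_label(a), "_", set_label(b))
  gene_set(intersect(a$gene_id, b$gene_id), name)
}

#' Difference of two gene sets
#'
#' @inheritParams intersect_sets
#' @return A `gene_set` with genes of `a` not present in `b`.
#' @export
difference_sets <- function(a, b, name = NULL) {
  check_columns(a, "gene_id", "Gene set `a`")
  check_columns(b, "gene_id", "Gene set `b`")
  name <- name %||% paste0(set_label(a), "_not_", set_label(b))
  gene_set(setdiff(a$gene_id, b$gene_id), name)
}

set_label <- function(x) {
  if ("set" %in% names(x) && nrow(x) > 0) x$set[1] else "set"
}

#' Select genes annotated with development-related GO terms
#'
#' Flags genes whose GO term names contain at least one of the keywords,
#' by case-insensitive substring match (so "developmental" matches the
#' keyword "development"). Term names are taken from a `go_terms` column
#' holding either a list of character vectors or semicolon-joined
#' strings.
#'
#' @param universe data frame of gene records with columns `gene_id` and
#'   `go_terms`.
#' @param keywords non-empty character vector of keywords; defaults to
#'   the development/growth/morphogenesis triple.
#' @param name name for the resulting set.
#' @return A `gene_set` of matching genes.
#' @export
#' @examples
#' u <- tibble::tibble(
#'   gene_id = c("g1", "g2"),
#'   go_terms = c("positive regulation of neuron growth", "ion transport")
#' )
#' development_filter(u) # g1 only
development_filter <- function(universe,
                               keywords = c("development", "growth",
                                            "morphogenesis"),
                               name = "development") {
  if (length(keywords) == 0) abort("`keywords` must be non-empty.")
  check_columns(universe, c("gene_id", "go_terms"), "Universe")
  terms <- universe$go_terms
  if (!is.list(terms)) terms <- strsplit(as.character(terms), ";", fixed = TRUE)
  pattern <- paste(stringr::str_escape(keywords), collapse = "|")
  hit <- purrr::map_lgl(terms, function(tt) {
    if (length(tt) == 0 || all(is.na(tt))) return(FALSE)
    any(stringr::str_detect(stringr::str_to_lower(tt),
                            stringr::str_to_lower(pattern)))
  })
  gene_set(universe$gene_id[hit], name)
}
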