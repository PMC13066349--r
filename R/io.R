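# Tabular and FASTA input/output. All tables are UTF-8,
# tab-separated, dot-decimal; report files start with a `#` metadata
# line. Readers validate structure and report offending values so
# malformed inputs fail early and loudly.

read_tsv_strict <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, comment = "#",
                  progress = FALSE, na = c("", "NA"))
}

#' Read / write a taxon ladder
#'
#' Tab-separated with columns `rank`, `taxon`, `age_mya`.
#'
#' @param path file path.
#' @return `read_ladder()` returns a validated ladder tibble.
#' @export
read_ladder <- function(path) {
  lad <- read_tsv_strict(path, readr::cols(
    rank = readr::col_integer(),
    taxon = readr::col_character(),
    age_mya = readr::col_double()
  ))
  validate_ladder(lad)
  lad
}

#' @param ladder ladder tibble.
#' @rdname read_ladder
#' @export
write_ladder <- function(ladder, path) {
  validate_ladder(ladder)
  readr::write_tsv(ladder, path)
  invisible(path)
}

#' Read / write a species-to-stratum map
#'
#' Tab-separated with columns `species`, `rank`.
#'
#' @param path file path.
#' @param ladder ladder used to validate ranks.
#' @export
read_species_map <- function(path, ladder = stratum_ladder()) {
  map <- read_tsv_strict(path, readr::cols(
    species = readr::col_character(),
    rank = readr::col_integer()
  ))
  validate_species_map(map, ladder)
}

#' @param map species map tibble.
#' @rdname read_species_map
#' @export
write_species_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' Read / write an ortholog hit table
#'
#' Tab-separated with columns `gene_id`, `species`, `identity`. Identity
#' must be a dot-decimal fraction in \[0, 1\]; values such as `"62%"` are
#' rejected with the offending line numbers.
#'
#' @param path file path.
#' @export
read_hits <- function(path) {
  hits <- read_tsv_strict(path, readr::cols(
    gene_id = readr::col_character(),
    species = readr::col_character(),
    identity = readr::col_character()
  ))
  check_columns(hits, c("gene_id", "species", "identity"), "Hits file")
  num <- suppressWarnings(as.numeric(hits$identity))
  bad <- which(is.na(num) | num < 0 | num > 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid identity value(s) at data line(s) %s (e.g. %s): expected a dot-decimal fraction in [0, 1].",
      paste(utils::head(bad, 5), collapse = ", "), hits$identity[bad[1]]
    ))
  }
  hits$identity <- num
  hits
}

#' @param hits hits tibble.
#' @rdname read_hits
#' @export
write_hits <- function(hits, path) {
  check_columns(hits, c("gene_id", "species", "identity"), "Hits table")
  readr::write_tsv(hits[, c("gene_id", "species", "identity")], path)
  invisible(path)
}

#' Read / write a gene-universe table
#'
#' Tab-separated with columns `gene_id`, `pai`, `di`, `is_gpcr`,
#' `is_brain_specific`, `is_development`, `ligand_type`, `go_terms`
#' (semicolon-joined term names). Missing PAI/DI are allowed and read as
#' `NA`. Duplicate gene ids are an error.
#'
#' @param path file path.
#' @export
read_universe <- function(path) {
  u <- read_tsv_strict(path, readr::cols(
    gene_id = readr::col_character(),
    pai = readr::col_integer(),
    di = readr::col_double(),
    is_gpcr = readr::col_logical(),
    is_brain_specific = readr::col_logical(),
    is_development = readr::col_logical(),
    ligand_type = readr::col_character(),
    go_terms = readr::col_character()
  ))
  if (anyDuplicated(u$gene_id)) {
    dup <- unique(u$gene_id[duplicated(u$gene_id)])
    abort(sprintf("Duplicate gene id(s): %s.",
                  paste(utils::head(dup, 5), collapse = ", ")))
  }
  u$go_terms[is.na(u$go_terms)] <- ""
  u
}

#' @param universe universe tibble.
#' @rdname read_universe
#' @export
write_universe <- function(universe, path) {
  check_columns(universe, "gene_id", "Universe")
  out <- universe
  if (is.list(out$go_terms)) {
    out$go_terms <- purrr::map_chr(out$go_terms, paste, collapse = ";")
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write a gene-set file
#'
#' One gene id per line, preceded by a header line `# set: <name>`.
#'
#' @param path file path.
#' @export
read_gene_set <- function(path) {
  lines <- readr::read_lines(path)
  header <- grep("^# set:", lines, value = TRUE)
  name <- if (length(header) > 0) {
    trimws(sub("^# set:", "", header[1]))
  } else {
    "set"
  }
  members <- trimws(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  gene_set(members, name)
}

#' @param set a `gene_set`.
#' @rdname read_gene_set
#' @export
write_gene_set <- function(set, path) {
  readr::write_lines(c(paste0("# set: ", set_label(set)), set$gene_id), path)
  invisible(path)
}

#' Read a codon-aligned pair from a FASTA file
#'
#' The file must contain exactly two records of equal length, a multiple
#' of 3 (codon mode). Gaps (`-`) are allowed and handled downstream by
#' [estimate_dnds()].
#'
#' @param path FASTA file path.
#' @return A list with `id_a`, `id_b`, `seq_a`, `seq_b`.
#' @export
read_codon_pair_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 2L) {
    abort(sprintf("Expected exactly 2 FASTA records, found %d.", length(seqs)))
  }
  widths <- Biostrings::width(seqs)
  if (widths[1] != widths[2]) {
    abort(sprintf("Aligned records differ in length (%s: %d, %s: %d).",
                  names(seqs)[1], widths[1], names(seqs)[2], widths[2]))
  }
  if (widths[1] %% 3 != 0) {
    abort(sprintf("Record %s: length %d is not a multiple of 3 (codon mode).",
                  names(seqs)[1], widths[1]))
  }
  list(
    id_a = names(seqs)[1], id_b = names(seqs)[2],
    seq_a = as.character(seqs[[1]]), seq_b = as.character(seqs[[2]])
  )
}

#' @param pair list with `id_a`, `id_b`, `seq_a`, `seq_b`.
#' @rdname read_codon_pair_fasta
#' @export
write_codon_pair_fasta <- function(pair, path) {
  x <- Biostrings::BStringSet(c(pair$seq_a, pair$seq_b))
  names(x) <- c(pair$id_a, pair$id_b)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a pipeline report to TSV and JSON
#'
#' Writes the enrichment table as a TSV (expected counts printed at two
#' decimals, full precision preserved in the JSON mirror) plus a JSON
#' file mirroring the whole report. Output contains no timestamps, so
#' re-running the pipeline on identical inputs yields byte-identical
#' files.
#'
#' @param report a `genevol_report` from [run_pipeline()].
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!inherits(report, "genevol_report")) {
    abort("`report` must be a genevol_report.")
  }
  meta <- sprintf(
    "# genevol %s\tidentity_threshold=%g\tdi_cut=%g\tneutrality_band=[%g,%g]",
    as.character(utils::packageVersion("genevol")),
    report$config$identity_threshold, report$config$di_cut,
    report$config$neutrality_band[1], report$config$neutrality_band[2]
  )
  if (!is.null(tsv_path)) {
    tbl <- tibble::as_tibble(report$enrichment) |>
      dplyr::mutate(
        expected = sprintf("%.2f", round_half_up(.data$expected, 2)),
        chi2 = sprintf("%.4f", .data$chi2),
        p = sprintf("%.6g", .data$p)
      ) |>
      dplyr::select("set", "background", "category", "observed",
                    "expected", "n", "chi2", "df", "p", "tier", "direction")
    readr::write_lines(meta, tsv_path)
    readr::write_tsv(tbl, tsv_path, append = TRUE, col_names = TRUE)
  }
  if (!is.null(json_path)) {
    payload <- list(
      meta = list(
        tool = "genevol",
        version = as.character(utils::packageVersion("genevol")),
        config = report$config[c("identity_threshold", "pai_focal_ranks",
                                 "pai_complement_ranks", "di_cut",
                                 "neutrality_band", "alpha_tiers")]
      ),
      enrichment = tibble::as_tibble(report$enrichment),
      di_shares = report$di_shares,
      pai_distributions = tibble::as_tibble(report$pai_distributions),
      log = report$log
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(tsv = tsv_path, json = json_path))
}
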