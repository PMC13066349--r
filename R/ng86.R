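# Nei-Gojobori (1986) codon counting: synonymous/nonsynonymous site
# fractions per codon, and pathway-averaged substitution counts per codon
# pair. The standard genetic code comes from Biostrings; everything else
# is computed here because the counting scheme IS the estimator.

.ng86_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

genetic_code <- function() Biostrings::GENETIC_CODE

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

translate_codon <- function(codon) {
  gc <- genetic_code()
  aa <- unname(gc[codon])
  if (any(is.na(aa))) {
    abort(sprintf("Not a valid ungapped codon: %s.",
                  paste(codon[is.na(aa)], collapse = ", ")))
  }
  aa
}

check_sense_codon <- function(codon, arg = "codon") {
  if (!is.character(codon) || any(is.na(codon)) || any(nchar(codon) != 3L)) {
    abort(sprintf("`%s` must be 3-letter codon strings.", arg))
  }
  codon <- toupper(codon)
  aa <- genetic_code()[codon]
  bad <- codon[is.na(aa)]
  if (length(bad) > 0) {
    abort(sprintf("Gapped or ambiguous codon(s) not allowed: %s.",
                  paste(unique(bad), collapse = ", ")))
  }
  stops <- codon[aa == "*"]
  if (length(stops) > 0) {
    abort(sprintf("Stop codon(s) not allowed: %s.",
                  paste(unique(stops), collapse = ", ")))
  }
  codon
}

# per-codon site fractions for all 61 sense codons, computed once.
# For each position, the synonymous fraction is
#   (# single-nucleotide changes to a sense codon coding the same aa) /
#   (# single-nucleotide changes to sense codons);
# mutations to stop codons are excluded from the denominator.
ng86_site_table <- function() {
  if (!is.null(.ng86_cache$sites)) return(.ng86_cache$sites)
  gc <- genetic_code()
  codons <- sense_codons()
  s <- vapply(codons, function(cod) {
    b <- strsplit(cod, "")[[1]]
    total <- 0
    for (p in 1:3) {
      syn <- 0L
      sense <- 0L
      for (nb in setdiff(BASES, b[p])) {
        nc <- b
        nc[p] <- nb
        nc <- paste(nc, collapse = "")
        if (gc[[nc]] != "*") {
          sense <- sense + 1L
          if (gc[[nc]] == gc[[cod]]) syn <- syn + 1L
        }
      }
      total <- total + syn / sense
    }
    total
  }, numeric(1))
  s <- unname(s)
  .ng86_cache$sites <- tibble::tibble(
    codon = codons,
    n_sites = 3 - s,
    s_sites = s
  )
  .ng86_cache$sites
}

#' Synonymous and nonsynonymous site counts per codon
#'
#' For each codon, each of the three positions contributes one site,
#' partitioned into a synonymous fraction (the proportion of possible
#' single-nucleotide changes at that position that preserve the encoded
#' amino acid, among changes leading to sense codons) and a complementary
#' nonsynonymous fraction. Changes creating stop codons are excluded from
#' the denominator.
#'
#' @param codons character vector of sense codons (no gaps, no stops).
#' @return A tibble with columns `codon`, `n_sites`, `s_sites`;
#'   `n_sites + s_sites == 3` for every codon.
#' @export
#' @examples
#' count_sites(c("TTT", "GCT", "ATG"))
count_sites <- function(codons) {
  codons <- check_sense_codon(codons, "codons")
  tab <- ng86_site_table()
  out <- tibble::tibble(codon = codons) |>
    dplyr::left_join(tab, by = "codon")
  out
}

# enumerate minimal mutational pathways between two codons and average
# synonymous / nonsynonymous step counts. Pathways passing through a stop
# codon are excluded; if every pathway is excluded, fall back to all.
ng86_pair_counts <- function(a, b) {
  key <- paste0(a, b)
  hit <- .ng86_cache$pairs[[key]]
  if (!is.null(hit)) return(hit)

  ba <- strsplit(a, "")[[1]]
  bb <- strsplit(b, "")[[1]]
  diff_pos <- which(ba != bb)
  d <- length(diff_pos)
  if (d == 0L) {
    res <- c(nd = 0, sd = 0)
  } else {
    gc <- genetic_code()
    orders <- perms(diff_pos)
    nd <- sd <- valid <- numeric(nrow(orders))
    for (i in seq_len(nrow(orders))) {
      cur <- ba
      ndi <- sdi <- 0
      ok <- TRUE
      for (p in orders[i, ]) {
        nxt <- cur
        nxt[p] <- bb[p]
        aa_cur <- gc[[paste(cur, collapse = "")]]
        aa_nxt <- gc[[paste(nxt, collapse = "")]]
        if (aa_nxt == "*" || aa_cur == "*") ok <- FALSE
        if (aa_cur == aa_nxt) sdi <- sdi + 1 else ndi <- ndi + 1
        cur <- nxt
      }
      nd[i] <- ndi
      sd[i] <- sdi
      valid[i] <- ok
    }
    use <- if (any(valid == 1)) valid == 1 else rep(TRUE, length(valid))
    res <- c(nd = mean(nd[use]), sd = mean(sd[use]))
  }
  if (is.null(.ng86_cache$pairs)) .ng86_cache$pairs <- new.env(parent = emptyenv())
  .ng86_cache$pairs[[key]] <- res
  res
}

# all orderings of a position vector (length <= 3 here)
perms <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- perms(x[-i])
    out <- rbind(out, cbind(x[i], sub))
  }
  out
}

#' Pathway-averaged substitution counts between codon pairs
#'
#' Counts the nonsynonymous (`nd`) and synonymous (`sd`) substitutions
#' separating two sense codons, averaged over all minimal mutational
#' pathways (orderings of the differing positions). Pathways that pass
#' through a stop codon are excluded from the average; if every pathway
#' passes through a stop, the average falls back to all pathways.
#' `nd + sd` always equals the number of differing positions.
#'
#' @param codon_a,codon_b character vectors of sense codons (recycled to
#'   a common length).
#' @return A tibble with columns `codon_a`, `codon_b`, `nd`, `sd`.
#' @export
#' @examples
#' count_differences("TTT", "GTC")
count_differences <- function(codon_a, codon_b) {
  codon_a <- check_sense_codon(codon_a, "codon_a")
  codon_b <- check_sense_codon(codon_b, "codon_b")
  n <- max(length(codon_a), length(codon_b))
  codon_a <- rep_len(codon_a, n)
  codon_b <- rep_len(codon_b, n)
  counts <- vapply(
    seq_len(n),
    function(i) ng86_pair_counts(codon_a[i], codon_b[i]),
    numeric(2)
  )
  tibble::tibble(
    codon_a = codon_a, codon_b = codon_b,
    nd = unname(counts["nd", ]), sd = unname(counts["sd", ])
  )
}
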