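# Independent oracles used to validate the implementation. These are
# deliberately written as plain exhaustive enumerations, sharing nothing
# with the package internals except the standard genetic code.

GC_TABLE <- Biostrings::GENETIC_CODE
SENSE <- names(GC_TABLE)[GC_TABLE != "*"]

# site fractions by direct enumeration of the 9 single-nucleotide
# neighbours of a codon
oracle_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  s_total <- 0
  for (pos in 1:3) {
    syn <- 0
    sense <- 0
    for (nb in c("A", "C", "G", "T")) {
      if (nb == b[pos]) next
      mutant <- b
      mutant[pos] <- nb
      mutant <- paste0(mutant, collapse = "")
      if (GC_TABLE[[mutant]] == "*") next
      sense <- sense + 1
      if (GC_TABLE[[mutant]] == GC_TABLE[[codon]]) syn <- syn + 1
    }
    s_total <- s_total + syn / sense
  }
  c(n = 3 - s_total, s = s_total)
}

# pathway counts by recursive depth-first enumeration of every ordering
# of the differing positions, tracking stop traversal
oracle_diffs <- function(a, b) {
  positions <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(positions) == 0) return(c(nd = 0, sd = 0))
  paths <- list()
  walk <- function(current, remaining, nd, sd, through_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(nd = nd, sd = sd, stop = through_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- current
      substr(nxt, p, p) <- substr(b, p, p)
      syn <- GC_TABLE[[current]] != "*" && GC_TABLE[[nxt]] != "*" &&
        GC_TABLE[[current]] == GC_TABLE[[nxt]]
      walk(nxt, setdiff(remaining, p),
           nd + as.numeric(!syn), sd + as.numeric(syn),
           through_stop || GC_TABLE[[nxt]] == "*" || GC_TABLE[[current]] == "*")
    }
  }
  walk(a, positions, 0, 0, FALSE)
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(
    nd = mean(vapply(paths[ok], `[[`, numeric(1), "nd")),
    sd = mean(vapply(paths[ok], `[[`, numeric(1), "sd"))
  )
}

# exact binomial upper tail by direct summation
oracle_binom_tail <- function(k, n, p) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}
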