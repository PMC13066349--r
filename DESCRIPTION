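Package: genevol
Title: Phylostratigraphic Age and Divergence-Index Analysis of Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the evolutionary properties of gene
    sets: phylostratigraphic age assignment (PAI) from ortholog best-hit
    tables against a 16-rank taxon ladder, pairwise dN/dS estimation by
    Nei-Gojobori (1986) counting with Jukes-Cantor correction and per-gene
    divergence-index (DI) aggregation with selection-mode classification,
    gene-set construction with GO-keyword filtering, and
    observed-versus-expected enrichment testing by 1-df chi-square
    goodness of fit. Includes seeded generators for synthetic ortholog
    tables, codon-alignment pairs evolved under a chosen dN/dS ratio, and
    a deterministic study-like gene universe, so the whole pipeline runs
    and is validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
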