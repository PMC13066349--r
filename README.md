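# genevol

Evolutionary characterization of gene sets in R: how old are the genes,
what kind of selection are they under, and do those properties differ
from a background set more than chance allows?

genevol is aimed at analyses in the style of phylostratigraphic
profiling of functionally defined human gene sets (e.g. a curated set
of receptor genes against all protein-coding genes). It provides three
things:

1. **Phylostratigraphic age index (PAI).** Each gene is dated on a
   16-rank taxon ladder (rank 1 = cellular organisms, ~4,100 Mya;
   rank 16 = the focal species) as the minimum rank among ortholog hits
   whose identity is ≥ 50% (closed bound, configurable). Lower PAI =
   older gene.
2. **Divergence index (DI).** For each gene, pairwise dN/dS against
   orthologs in four hominids (chimpanzee, bonobo, gorilla, orangutan
   by default), estimated by Nei–Gojobori (1986) counting with
   Jukes–Cantor correction,

       DI = (1/n) Σᵢ (dN/dS)ᵢ ,

   with pairs excluded when dS = 0. DI ≪ 1 indicates stabilizing
   (purifying) selection; DI ≈ 1 neutrality; DI > 1 diversifying
   selection.
3. **Enrichment tests.** Observed counts of set genes in a category
   (an age rank, a DI threshold) against the count expected from a
   background distribution, `exp = n·k/N`, tested by a two-cell 1-df
   chi-square goodness of fit without continuity correction; plus a
   2×2 independence test for cross-classifications.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()`
and `glance()` methods on test objects, `autoplot()` on distributions
and enrichment tables. Seeded generators (`generate_universe()`,
`simulate_codon_pair()`, `generate_paperlike_fixture()`) produce
synthetic inputs with known planted structure so the whole pipeline
runs and is validated without external databases.

## Worked example

Run the full pipeline on the deterministic study-like fixture (19,504
genes; an 80-gene receptor set nesting 67 GPCRs inside a 420-gene GPCR
superfamily set):

```r
library(genevol)

fx <- generate_paperlike_fixture()
report <- run_pipeline(list(
  genes = fx$genes, hits = fx$hits, sets = fx$sets,
  species_map = fx$species_map, ladder = fx$ladder
))
report
#> genevol report: 19504 genes, 6 sets
#> Enrichment tests:
#> # A tibble: 6 × 8
#>   set                 background category observed expected     n        p tier
#> 1 Receptors_80        universe   PAI = 6        37    13.1     80 5.97e-13 p<0.…
#> 2 allGPCR_420         universe   PAI = 6       152    69.0    420 7.82e-28 p<0.…
#> 3 Receptors_80_allGP… allGPCR_4… PAI = 6        35    24.2     67 6.27e- 3 p<0.…
#> 4 Receptors_80_not_a… universe   PAI in …        6     2.29    13 7.03e- 3 p<0.…
#> 5 Receptors_80        universe   DI <= 0…       45    35.8     80 3.77e- 2 p<0.…
#> 6 Receptors_80_allGP… allGPCR_4… DI <= 0…       38    27.8     67 1.11e- 2 p<0.…
```

Reading row 1: 37 of the 80 receptor genes date to rank 6 (the
Vertebrata stage), while only 13.14 would be expected if the set
followed the genome-wide age distribution — a strong enrichment
(p < 0.001). Row 5 shows the same set is also enriched for genes under
strong purifying selection: 45 of 80 at DI ≤ 0.25 (56.3%) against 35.8
expected (p < 0.05). The report also carries the DI shares per set:

```r
report$di_shares
#> # A tibble: 4 × 5
#>   set                        cut count total percent
#> 1 universe                  0.25  8718 19504    44.7
#> 2 Receptors_80              0.25    45    80    56.3
#> 3 allGPCR_420               0.25   174   420    41.4
#> 4 Receptors_80_allGPCR_420  0.25    38    67    56.7
```

and a 2×2 test showing development-annotated genes concentrate in the
low-DI half of the receptor set (observed 18 vs 12.94 expected,
p < 0.05). `autoplot(report$pai_distributions)` draws the comparative
age distributions.

Individual stages are ordinary functions on tables:

```r
estimate_dnds("TTTGCTAAA", "TTCGCTAAA")
#> # A tibble: 1 × 13
#>   gene_id species n_codons n_discarded n_sites s_sites    nd    sd    pn    ps
#> 1 <NA>    <NA>           3           0    7.33    1.67     0     1     0   0.6
#> # dn = 0, ds = 1.21, ratio = 0
```

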