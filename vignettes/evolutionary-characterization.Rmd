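---
title: "Evolutionary characterization of gene sets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary characterization of gene sets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genevol)
```

This vignette explains the models and procedures behind genevol, the
assumptions they make, the parameters that matter, and the design
choices taken where the methodology left room. It is written for a
reader who wants to know *why* the package computes what it computes.

## The two evolutionary characteristics

### Phylostratigraphic age index (PAI)

Phylostratigraphy dates the origin of a gene by the most distant lineage
in which an ortholog can still be detected. The package uses a ladder of
16 taxonomic stages on the human lineage (`stratum_ladder()`), from
cellular organisms (rank 1, ~4,100 Mya) through Eukaryota, Metazoa,
Chordata, Craniata, Vertebrata, Euteleostomi, Mammalia, Eutheria,
Euarchontoglires, Primates, Haplorrhini, Catarrhini, Hominidae and Homo
down to *Homo sapiens* (rank 16, ~0.35 Mya). Each ortholog hit is a
`(gene, subject species, identity)` record; a species map places every
subject species at the rank of the stage where its lineage split from
the focal lineage. A gene's PAI is then

> the minimum rank among species whose hit identity is at least the
> threshold (0.5 by default, a closed bound: exactly 50% qualifies).

Low PAI means old gene. A gene with no qualifying hit outside the focal
species receives the focal rank (16): nothing in the procedure
distinguishes "assigned young" from "unassigned", and the ladder's
terminal rank is precisely "found only in the focal species".

Assumptions and limitations worth keeping in mind:

* Identity values are consumed as precomputed fractions (the style of
  best-hit similarity databases); the package does not align sequences
  to compute them, so whether identities were derived from protein or
  DNA alignments is the caller's concern. Both conventions exist in
  practice; the assignment rule is agnostic, but mixed conventions in
  one hit table would be a silent inconsistency.
* The species map is supplied data. The shipped default is a synthetic
  one-representative-per-stage convenience; real analyses should derive
  the map from the taxonomy of their ortholog database.
* Homology detection fails more often for fast-evolving genes, which
  biases ages of such genes towards youth. No correction for this is
  attempted; it is a known limitation of the method family.

### Divergence index (DI)

The DI of a gene is the arithmetic mean of pairwise dN/dS ratios
between the gene and its orthologs in a small panel of closely related
species (by default four hominids: chimpanzee, bonobo, western lowland
gorilla, Sumatran orangutan). dN/dS below 1 indicates purifying
(stabilizing) selection, near 1 neutrality, above 1 diversifying
selection.

The pairwise estimator is Nei–Gojobori (1986) counting with
Jukes–Cantor correction, chosen because it is deterministic,
closed-form, and verifiable against exhaustive enumeration (the test
suite checks all 61 sense codons and all 61×61 codon pairs against an
independent enumerator). The estimator sits behind a small interface
(`estimate_dnds()`), so a likelihood-based variant could be added
without touching the rest of the pipeline. Per codon, each of the three
positions contributes one site split into synonymous and nonsynonymous
fractions (mutations to stop codons are excluded from the denominator);
per differing codon column, substitutions are averaged over all
orderings of the changed positions, excluding pathways that pass
through a stop codon and falling back to all pathways when every one is
excluded. Columns containing gaps or non-ACGT symbols are discarded and
counted. Proportions are corrected with `d = -(3/4)·ln(1 − 4p/3)`;
proportions at or above 0.75 have no finite correction and raise an
error rather than returning a fabricated value.

Numerical edge cases are resolved as follows:

* **dS = 0 for a pair** (common between very close species): the
  pair's ratio is undefined and the pair is excluded from the DI mean,
  with the exclusion logged. Fabricating 0/0 as 0 or infinity would
  bias the mean in opposite directions; exclusion is the only neutral
  choice. If every pair is excluded, the gene's DI is reported missing.
* **Selection-mode classification**: "DI ≈ 1" needs a width to be
  operational; the default neutrality band is [0.9, 1.1] and is
  configurable. Genes discussed in typical analyses sit far outside
  any reasonable band (e.g. DI 0.026 or 1.84), so the conclusions are
  insensitive to the width.

## Gene sets and the development filter

Gene sets are tidy tibbles (`set`, `gene_id`), and the set algebra
(`intersect_sets()`, `difference_sets()`) is ordinary set algebra. The
development filter selects genes whose GO term names contain at least
one of the keywords *development*, *growth*, *morphogenesis* by
case-insensitive substring match — so "developmental pigmentation"
matches — mirroring how keyword screens over annotation-chart exports
are done in practice. Matching is on term names only, not definitions.
Flags that originate in external services (GPCR superfamily
membership, brain-specific expression) are consumed as annotation
columns, never computed: recomputing them would drag in external
dependencies and version drift without changing the analysis.

## Enrichment statistics

For a set of `n` genes and a category (an age rank, or a DI threshold),
the expected count under a background set is `n × k/N`, where `k` of
`N` background genes fall in the category. Observed versus expected is
tested with a **two-cell 1-df chi-square goodness of fit without
continuity correction**:

    chi2 = (obs − exp)²/exp + ((n−obs) − (n−exp))²/(n−exp)

and the 2×2 cross-classification (development annotation × DI
threshold) uses the corresponding 4-cell statistic with 1 df, expected
cells from the margins under independence. This is the construction
that reproduces the full pattern of published significance tiers for
this analysis family, which a Yates-corrected or Fisher variant does
not; the test suite pins the behaviour against `chisq.test(...,
correct = FALSE)` as an independent oracle. Genes with a missing value
under a category predicate are excluded from both margins and the
exclusions logged. p-values are reported exactly and additionally
binned into the conventional tiers (p < 0.05, < 0.01, < 0.001); no
multiple-testing correction is applied, because the analysis design
makes a handful of pre-planned comparisons rather than a scan.
`binomial_tail()` provides an exact upper tail for ad-hoc "how
surprising is this clustering" questions; choosing the null proportion
is deliberately left to the analyst.

Reporting conventions: expected counts print at two decimals and
percentage shares at one decimal, both rounded half-away-from-zero
(`round_half_up()`), the convention under which 45/80 prints as 56.3%.
Full precision is preserved in the underlying tibbles and JSON.

## The synthetic-data generators

The package validates itself on generated data with known planted
structure, at three levels of realism.

**`generate_universe()`** draws a gene universe: PAI ranks from a
16-category distribution, DI values from a mixture, annotation flags
from per-gene Bernoulli draws with optional odds-multiplier enrichment
against a conditioning predicate. Defaults are anchored to the
published genome-wide landmarks: roughly 33% of genes at rank 1, 16.4%
at rank 6, 13.9% at rank 7, under 2% at ranks 4–5, a thinning tail
elsewhere; the DI default is a single log-normal (meanlog −1.2776,
sdlog 0.816) solving exactly for 44.7% of mass at DI ≤ 0.25 and 5.85%
above 1. Ortholog hit tables are constructed so that `assign_pai()`
provably recovers every planted age: one qualifying hit at the planted
rank, optional qualifying hits at shallower ranks (which cannot change
the minimum), optional sub-threshold decoys at deeper ranks (which the
threshold removes). What this generator does *not* emulate: identity
values correlated with age, multiple hits per species, lineage-specific
detection failure — recovery being exact by construction is a test of
the assignment logic, not of ortholog detection.

**`simulate_codon_pair()`** evolves a uniformly drawn sense-codon
sequence by single-nucleotide proposals, rejecting stops, accepting
synonymous changes with probability `min(1, 1/ω)` and nonsynonymous
with `min(1, ω)`, until the realized synonymous divergence reaches the
target dS. The default transition:transversion proposal weight is 1
because the counting estimator applies no transition-bias correction;
simulating with strong transition bias and estimating with an
uncorrected counter would conflate generator realism with estimator
bias. Calibration (fixed in the tests): at 3,000 codons, target dS
0.08 and 50 replicates per ω, mean estimated ratios are strictly
increasing over ω ∈ {0.1, 0.5, 1.0, 2.0} and the ω = 1 mean falls in
[0.85, 1.15]. The simulator has no indels, no rate variation among
sites, and no codon-usage bias.

**`generate_paperlike_fixture()`** is fully deterministic: a universe
of 19,504 genes that plants, exactly, every published marginal count of
the receptor-gene analysis the package emulates — set sizes 80/420/67/
13/23; 6,350 genes at rank 1, 3,203 at rank 6, 2,708 at rank 7, 3,443
at ranks 7–8; 8,718 genes (44.7%) at DI ≤ 0.25 and 1,141 (5.85%) above
1; 37/80, 152/420, 35/67 at rank 6, 6/13 at ranks 7–8, 45/80, 174/420,
38/67 at DI ≤ 0.25; and 23 development-annotated receptor genes
splitting 18/5 across the DI boundary. Counts the analysis does not pin
down (per-rank counts the published distributions only show
graphically, the DI value grids, ligand-type fill) were chosen once as
plausible values satisfying every pinned marginal, and are not tuned:
the fixture's purpose is that the pipeline, run end to end, reproduces
the published expected counts (13.14, 68.97, 24.25, 2.29, 35.8, 12.94,
10.06) and significance tiers deterministically. All gene ids are
synthetic; the fixture emulates the shape of the study's gene tables,
not their content, and passing on it shows the computations are right —
not that real orthology data would yield these numbers.

## The pipeline

`run_pipeline()` chains the stages: PAI assignment from hits →
DI (computed from codon alignments when supplied, otherwise taken from
a precomputed `di` column, the common case when divergence estimates
come from an upstream tool) → derived set construction (intersection,
difference, development filter) → distributions → enrichment tests →
the 2×2 development partition. Every filtering decision — genes without
hits, pairs excluded for dS = 0, discarded alignment columns, genes
dropped for missing values — is recorded in the report log. Reports
contain no timestamps, so identical inputs and configuration produce
byte-identical TSV/JSON output.

Problem sizes used in the validation suite — the 19,504-gene fixture
for the deterministic end-to-end checks, 1,500–2,000-gene universes for
recovery properties, 3,000-codon pairs × 50 replicates for estimator
calibration — were chosen as the smallest sizes at which the planted
signals are unambiguous (binomial sampling error well inside the
asserted bounds).

## Known limitations

* NG86 counting underestimates dN/dS when transition bias or extreme
  codon usage is strong; the estimator interface is the extension point
  for a maximum-likelihood variant.
* PAI inherits all biases of homology detection; the package measures
  the assignment rule, not detection sensitivity.
* The enrichment machinery tests one category against one background
  per call; it is not a general contingency-table or GSEA framework.
* Printed gene-level DI values from the emulated study (e.g. 1.84 for
  the most divergent receptor) depend on the original sequence data and
  are used only as classification examples, never as regression
  targets.
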