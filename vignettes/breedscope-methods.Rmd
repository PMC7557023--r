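---
title: "Methods: pedigree, ROH and variant-filter analytics in breedscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree, ROH and variant-filter analytics in breedscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

breedscope quantifies the loss of genetic diversity in a closed dog-breed
population from three substrates — registry pedigrees, SNP-array genotypes
and joint cohort/control whole-genome variant tables — and ships a
synthetic-data generator so that every stage can be exercised and verified
without access to proprietary registry data.  This vignette documents the
models, the parameters that matter, the numerical choices, and the limits
of what the synthetic data can demonstrate.

## Pedigree model

A pedigree is a directed acyclic parent graph.  `Pedigree()` normalises
unknown-parent tokens, materialises parents that are referenced but never
recorded as founder records, and rejects duplicated ids, self-parenting,
cycles and animals used both as sire and as dam.  All recursive quantities
are evaluated in a topological (parents-before-offspring) order.

### Kinship by the tabular method

`kinshipTabular()` builds the coancestry matrix with the classical
recurrence: for an animal $i$ with parents $s$ and $d$,

$$f_{ij} = \tfrac12 (f_{sj} + f_{dj}), \qquad
  f_{ii} = \tfrac12 (1 + f_{sd}),$$

where an unknown parent contributes 0, i.e. it is treated as a unique,
unrelated, non-inbred founder.  The paper trail for every derived quantity
runs through this matrix: the inbreeding coefficient is
$F_i = f_{\mathrm{sire}(i),\mathrm{dam}(i)}$ (exactly 0 with an unknown
parent, and equal to $2 f_{ii} - 1$), and the mean kinship of animal $i$
against a reference population $R$ is
$MK_i = |R|^{-1} \sum_{j \in R} f_{ij}$.

Two conventions are deliberate and switchable:

* **Self term in MK.**  The self-coancestry $f_{ii}$ is included when
  $i \in R$ (`includeSelf = TRUE`), the usual convention in
  conservation-genetics breeding management, where a candidate's own
  inbreeding should count against it.
* **MK colour groups.**  `mkColorGroups()` partitions animals at 0.31 and
  0.32 by default — the cutpoints used in practice to flag relatively
  unrelated (green) versus over-related (orange) breeding candidates —
  with boundary values assigned to the middle (yellow) group, i.e. a
  closed interval.

The test suite validates the tabular recurrence against an independent
path-counting oracle that sums $(1/2)^{L_1+L_2+1}(1+F_A)$ over common
ancestors $A$ and pairs of ancestral paths that share only $A$, on random
pedigrees of up to 30 animals at a tolerance of $10^{-12}$.

### Founders, contributions, completeness

A *founder* is an animal with both parents unknown.  Because a registry
typically contains many dead-end records, `findFounders()` additionally
requires at least one descendant in the most recent birth cohort; this
"contributing founder" definition is our documented choice where the field
uses the term loosely.  `founderContribution()` computes expected genetic
contributions by the recursion "own contribution = mean of parental
contributions", which conserves mass: over all founders the contributions
sum to the cohort's known-ancestry fraction (exactly 1 for a fully known
pedigree).  The test suite checks the recursion against a Monte-Carlo
gene-dropping estimate.

`pedigreeCompleteness()` uses the simple known-slot proportion over $g$
generations (denominator $2 + 4 + \dots + 2^g$), counting a duplicated
ancestor once per pedigree slot.  The harmonic (MacCluer-style) variant is
not implemented; for the deep, nearly complete pedigrees this package
targets the two hardly differ, and the simple proportion is the more
transparent diagnostic.

### Demographic statistics

A *litter* is the set of offspring sharing sire, dam and birth date.  The
*popular-sire threshold* defaults to the size of five litters at the
observed mean litter size, rounded up (33 puppies at a mean litter of
6.5).  The *generation interval* is the mean parental age at offspring
birth in years.  `longevityStats()` summarises age at death per birth
year and keeps only years with strictly more than `min_records` dated
animals (default 100), because sparsely recorded or still-living cohorts
bias longevity upward.  Dates are ISO-8601; bare years are taken as
July 1 for interval arithmetic.

`surveySummary()` counts dogs, not reports: a dog with several disorders
counts once in the any-condition total and once per category, so category
counts may sum beyond the number of affected dogs.  Percentages are
recomputed from raw counts and rounded to one decimal only at
presentation.

## SNP-array genotypes and runs of homozygosity

`GenotypeMatrix` extends `SummarizedExperiment`: one `calls` assay of
allele-2 dosages (0/1/2/`NA`) with the SNP map in `rowData`, sorted with
strictly increasing positions per chromosome.  `readPlinkText()` parses
the PLINK text PED/MAP dialect and codes the minor allele as the counted
allele (ties broken toward the alphabetically later allele).

`mergeArrays()` intersects two arrays by chromosome and position,
reconciles allele coding including strand flips for unambiguous allele
pairs, drops A/T and C/G SNPs whose minor-allele frequency exceeds 0.4 on
either array (a strand flip is then statistically unresolvable), and
removes SNPs whose post-merge missingness is 0.1 or more (strictly lower
passes).  `qcFilter()` then keeps biallelic SNPs on the 38 canine
autosomes and removes Hardy–Weinberg outliers at `p < 1e-4`, using a
hand-written two-sided conditional exact test (`hweExactTest()`,
evaluated by a stable probability-ratio recurrence and validated against
full enumeration).

### ROH detection

`callRoh()` implements the standard sliding-window scan: windows of 50
consecutive SNPs tolerating at most 1 heterozygous and 5 missing calls;
a SNP is ROH-eligible when at least 5% of the windows covering it are
homozygous; maximal runs of eligible SNPs become segments, split where
adjacent SNPs are more than 1000 kb apart, and retained when they hold at
least `minSnps` SNPs, span at least 1 Mb, and are at least as dense as
one SNP per 20 kb.  Segment coordinates are the 1-based positions of the
first and last SNP, inclusive, with length $(\mathrm{end} -
\mathrm{start} + 1)/1000$ kb — the convention of the toolkit reports this
mirrors.  The caller is validated against a brute-force implementation
that enumerates every window literally.

`minSnpsForRoh()` gives the marker minimum that keeps chance ROH below a
fraction $\alpha$ of the dataset-wide tests:
$\lceil \ln(\alpha / (n_\mathrm{SNP} \, n_\mathrm{ind})) /
\ln(1 - \bar h) \rceil$.  With a 132,711-SNP panel on 1203 dogs and mean
heterozygosity 0.27 this yields 70.  The mean heterozygosity is a user
input (`hetMean`); it should be estimated from the QC'd data when not
known.

$F_\mathrm{ROH}$ divides an individual's total ROH length by the covered
autosomal span, defined as the sum over autosomes of first-to-last
retained SNP distance.  `rohLengthClasses()` bins at 1/2/4/8/10 Mb — the
balance of short (ancient inbreeding) versus long (recent inbreeding)
segments.  `perChromosomeSummary()` reports the per-dog mean fraction of
the chromosome's covered span in ROH (per-dog mean rather than a
population union — our documented choice).  `rohSharingScan()` computes,
for every SNP, the fraction of individuals whose ROH contains it, and
returns maximal intervals exceeding a query threshold; this is the scan
that exposes breed-wide consensus homozygosity regions.

`ibsDistance()` is $1 -$ mean shared-allele fraction over jointly called
SNPs, and `classicalMds()` is Torgerson scaling (double-centred squared
distances, eigendecomposition via `stats::cmdscale`), exact for Euclidean
inputs; negative eigenvalues are reported but never used.

## The variant filter cascade

Filters operate on an aggregated table (one row per biallelic variant)
with cohort/control frequencies, allele counts and carrier counts, built
from per-sample genotypes, a pre-aggregated TSV, or a multi-sample VCF.
Frequencies are computed over non-missing samples only; all threshold
comparisons are strict, and rounding to four decimals happens only in
reports.

* `privateVariantFilter()`: every cohort sample carries at least one
  alternative allele (a missing cohort genotype disqualifies) and the
  controls carry none.
* `rareVariantFilter()`: at least one cohort allele, zero control
  alleles.  Private variants are by construction a subset.
* `candidateGeneFilter()`: annotation-based set intersection with a gene
  list; unannotated records drop.
* `enrichmentFilter()`: control frequency strictly inside (0, 0.10) and
  cohort frequency strictly above twice the control value.  Because rare
  variants have zero control frequency, a rare table can never pass the
  enrichment filter — the two cascades answer different questions.

Consequence annotation is consumed, never predicted; the controlled
vocabulary separates coding classes (synonymous, missense, frameshift,
in-frame insertion/deletion, nonsense) from non-coding, and
protein-changing is coding minus synonymous.

## Mitochondrial summaries

`heteroplasmy()` is the raw alt-read percentage of total depth (100% =
homoplasmy); no strand-bias correction is applied.  `assignHaplogroup()`
is a generic definition-table matcher: the deepest node of a
single-rooted tree whose full defining-variant chain is contained in the
sample's variants, with ambiguity (equally deep multiple matches) treated
as a definition error.  Published canine haplogroup nomenclatures are not
encoded; the shipped `haplogroups_demo.tsv` is an illustrative tree and
users supply real definition tables.

## The synthetic-data generator

`simConfig()` encodes the stylised history of a giant breed founded in
the 19th century: 22 founders (10 males, 12 females), years 1920–1959 by
default, a severe 1946 bottleneck sparing 17 dogs, truncated-Poisson
litters with mean 6.5, parental recruitment between 2 and 6 years (a
roughly 4-year generation interval), normal lifespans (mean 8.2, sd 2.2
years), and popular-sire skew.  Sire usage is drawn from a
gamma-weighted (Dirichlet) distribution whose concentration is `1/sireSkew`;
0 means uniform usage and larger values concentrate matings on few
males — a single interpretable knob.  Eight litters per year keeps the
default population at a size (a few thousand animals) where the full
kinship matrix is computed in seconds.

`geneDrop()` drops founder alleles through the pedigree: founder
haplotypes are Bernoulli draws from Beta(0.5, 0.5) allele frequencies (a
realistic folded spectrum), and each gamete recombines under a Haldane
(no-interference) model at 1 cM/Mb on ten 60-Mb autosomes by default.
Founder-haplotype origin labels are tracked, so each animal's *realised*
autozygous genome fraction — the quantity $F_\mathrm{PED}$ estimates in
expectation — is returned alongside the genotypes.  An animal with an
unknown parent receives a fresh founder-like haplotype on that side,
matching the kinship convention for unknown parents.

`simulateVariantTable()` plants private, rare and enriched variants that
satisfy the filter definitions *by construction* (e.g. planted enriched
variants receive a realised control frequency strictly inside the window
and a cohort count strictly above the doubled control frequency), against
a background of variants common in controls; `simulateSurvey()` draws
independent Bernoulli condition indicators.  All generators are
deterministic given their seed and restore the caller's RNG state.

**What the synthetic data do not emulate.**  Linkage disequilibrium
beyond pedigree-induced IBD, genotyping error and missingness patterns,
array ascertainment bias, real canine chromosome lengths and
recombination maps, selection on phenotypes, and population structure
between countries.  Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under the stylised model — not
robustness to artefacts of real array or sequencing data.

## Numerical choices and test problem sizes

* Kinship, contributions and completeness are exact recursions; the only
  tolerances are the $10^{-12}$ oracle comparisons.
* The HWE exact test accumulates configurations with probability at most
  $(1 + 10^{-10})$ times the observed probability, absorbing
  floating-point ties in the two-sided sum.
* Minor-allele ties in PLINK parsing break toward the alphabetically
  later allele; merge conflicts drop the SNP rather than guess.
* Dates without a day resolve to July 1; birth cohorts are calendar
  years.
* Tests run at sizes chosen to exercise every code path in seconds:
  pedigrees of 10–40 animals for oracle equivalence (100 replicates),
  500-SNP chromosomes for ROH brute-force equivalence (100 replicates),
  10,000 SNPs over two 50-Mb chromosomes for the full-sib gene-dropping
  calibration (30 independent families), and 20,000 SNPs over eight
  25-Mb chromosomes for the pedigree-versus-genomic inbreeding rank
  correlation on 200 animals.

## Known limitations

* `kinshipTabular()` builds a dense matrix: fine for tens of thousands
  of animals, not for registry-scale millions; `subset` restricts the
  computation to the ancestor closure of a cohort of interest.
* The ROH caller follows the sliding-window definition exactly; it does
  not implement LD pruning, phasing, or model-based (HMM) autozygosity.
* The haplogroup matcher requires unambiguous definition tables and does
  not reconcile D-loop-only with whole-mitogenome nomenclatures.
* `variantTableFromVcf()` expects GT fields and biallelic rows after
  expansion; structural variants are out of scope.
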