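---
title: "LD-aware annotation enrichment by chromosome-bound circular permutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-aware annotation enrichment by chromosome-bound circular permutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circenrich)
```

## The problem

Genome-wide association studies (GWAS) report thousands of trait-associated
SNPs, and a standard way to interpret them is to ask which functional
annotations — genic features, conserved elements, chromatin states — contain
more (or fewer) of them than expected. The catch is the null model. SNPs are
not placed uniformly along the genome, annotations are strongly clustered,
and every SNP drags a neighborhood of linkage-disequilibrium (LD) partners
with it. A null that samples SNPs uniformly at random ignores all three
facts and can badly overstate significance when the trait-associated SNPs
are positionally clustered, as real GWAS hits are (association signals come
in LD blocks).

`circenrich` implements the enrichment framework built around a
*chromosome-bound circular permutation* null: the vector of
trait-association labels is rotated along the positional SNP order within
each chromosome, wrapping at the chromosome end. A rotation preserves,
exactly,

* the number of associated SNPs per chromosome,
* the relative spacing (clustering) of the labels,
* the positions of SNPs, annotations, and the LD structure around every SNP,

while breaking any alignment between labels and annotations. Overlap counts
of the rotated label sets form an empirical null distribution from which
odds ratios, confidence intervals and p-values are read off without
distributional assumptions.

## Overlap semantics

SNP positions are 1-based (dbSNP/VCF convention); annotation intervals are
0-based half-open BED intervals, so a position $p$ lies in $[s, e)$ iff
$s < p \le e$. A SNP *hits* an annotation if it **or any of its LD
partners** lies inside one of the annotation's intervals; SNPs without
partners are analyzed on their own. LD partners are pairs with $r^2$
strictly above a threshold (0.9 by default, 0.7 as the liberal alternative)
at most 250 kb apart on either side, on the same chromosome. Incidence is
binary: several overlapping intervals or several partners inside still count
as one hit.

The incidence of every SNP against every annotation is precomputed once into
a boolean `overlap_matrix`. This is the central performance contract: a
permutation then only rotates the label vector and re-counts `TRUE` rows —
it never touches intervals again. Internally the package goes one step
further and computes, per chromosome and annotation, the hit count for
*every possible offset* via FFT circular cross-correlation, so 20,000
permutations reduce to table lookups. The counts are integers by
construction; the implementation rounds the FFT output and verifies
integrality, and the test suite checks the fast path cell-for-cell against a
brute-force relabel-and-recount oracle that re-derives LD-expanded overlap
from the raw intervals.

## Inference

For each annotation with observed hit count $a$ among $n$ associated SNPs
and null counts $c_1, \dots, c_B$ with mean $\bar c$:

* **Odds ratio** $\mathrm{OR} = \dfrac{a\,(n - \bar c)}{(n - a)\,\bar c}$ —
  the cross-product of overlaps/non-overlaps in the real versus null data.
  Null cells may be non-integer (they are means). A zero denominator with a
  positive numerator is reported as `Infinity`, matching how sparse
  annotations behave; no continuity correction is applied by default
  (a Haldane–Anscombe +0.5 mode exists behind a flag).
* **Confidence interval**: the null-count quantiles are substituted into the
  null cell of the same formula — the upper quantile gives the lower bound,
  the lower quantile the upper bound, so the interval always brackets the
  point estimate. The default `ci_mode` uses the 2.5th/97.5th percentiles of
  the null counts, a conventional 95% interval. A literal mode that uses the
  5th and 95th *largest* of the null counts is preserved for fidelity
  experiments: with 20,000 permutations those order statistics correspond to
  a ≈99.95% band, which is why it is not the default.
* **Empirical p-value**: the proportion of permuted genomes at least as
  extreme as the observation, in the direction of the observed effect (ties
  count as extreme; a strict mode exists). With zero exceedances the value
  is reported as the bound $< 1/B$ — at 20,000 permutations, $<5\times
  10^{-5}$. The default directional p is the quantity enrichment reports
  conventionally print, but note it picks its tail from the data: under a
  true null it calls either tail at 0.05 about 10% of the time. The
  `two_sided_doubled` mode doubles the directional p and is the calibrated
  choice; the calibration tests use it, and we recommend it whenever p-values
  are compared against a fixed error rate.
* **Fold enrichment** $a/\bar c$ is reported alongside; for rare annotations
  (both hit fractions below 5%) it agrees with the odds ratio to within a
  few percent.
* **Bonferroni**: the family-wise threshold is $\alpha/\text{(number of
  annotations)}$ — for the canonical 58-annotation family at
  $\alpha = 0.05$, $8.62\times10^{-4}$.

### The sampling comparison null

The conventional method the permutation approach is benchmarked against
draws random background SNP sets of the same size as the associated set,
weighted by genotyping-platform group so the background matches the
platforms that discovered the associations: per-group counts follow
largest-remainder rounding of the group proportions observed among the
associated SNPs, sampling is without replacement, and groups are processed
disjointly in fixed alphabetical order (a multi-platform SNP counts once).
Background SNPs keep their LD expansion — their rows of the same overlap
matrix. Inference here is *theoretical*: Wald intervals
$\exp(\ln \mathrm{OR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d})$ and normal
p-values on $\ln \mathrm{OR}$, against the mean hit count over (by default)
100 samples. On genomes without clustering or LD the two methods agree
closely; under clustering the sampling intervals are narrower
(anti-conservative), which is the motivation for the permutation method.
Background samples may include associated SNPs (exclusion is a flag).

### The joint model

Enrichments of single annotations are confounded by co-location: chromatin
states, genic features and conservation overlap each other. The package
therefore fits a stepwise logistic regression of association status (1 =
associated, 0 = not) on all annotation incidences at once. Platform
indicators form the *empty model* and are forced — never candidates for
removal. Selection is bidirectional: at each step the single addition or
removal with the largest AIC reduction is taken, halting when AIC would
rise; ties break lexicographically by annotation name for determinism, and
the step log is retained. For every term the estimate, standard error,
beta-coefficient (estimate/SE, i.e. the Wald z) and Wald p-value are
reported. Model-level summaries: McFadden pseudo-$r^2$
($1 - \ell_{full}/\ell_{empty}$), McKelvey–Zavoina pseudo-$r^2$
($\mathrm{Var}(\hat\eta)/(\mathrm{Var}(\hat\eta) + \pi^2/3)$), and the
deviance (likelihood-ratio) test of the final model against the empty one.
Separation is detected and flagged, never silently returned. Tautologically
trait-associated annotations (disease-gene catalogs) should be passed to
`exclude=` so they cannot dominate the model.

Distance to the nearest *upstream* transcription start site can be added as
a quantitative covariate: for each SNP the minimum, over the SNP and its LD
partners (an SNP-only mode exists), of the distance to the nearest TSS it
lies 5′ of, respecting strand. The covariate enters untransformed in base
pairs by default (`log1p` is a flag). SNPs with no upstream TSS on their
chromosome are missing; the model replaces them by a cap — the largest
finite observed distance by default — and reports how many were capped.
Both choices (LD-expanded minimum, capped missing values) are decisions this
package makes explicit because the procedure is otherwise underdetermined;
the alternatives are exposed as configuration.

## The synthetic-data generator

Every stage is testable offline against genomes that reproduce the
statistical structure the method must respect:

* **SNP positions**: a Poisson cluster process (uniform cluster centers,
  Poisson cluster sizes around a mean of 20 SNPs, geometric within-cluster
  gaps with mean 300 bp) — over-dispersed inter-SNP gaps like real marker
  maps, verified by an index-of-dispersion test. Default scale: 3
  chromosomes × 20,000 SNPs on 20 Mb each, matching the ~1 marker/kb density
  of a genome-wide panel.
* **LD**: chromosomes tiled into exponential blocks (mean 20 kb, the scale
  of human haplotype blocks); all intra-block pairs draw $r^2$ uniform on
  [0.5, 1], and only pairs passing the strict threshold and the 250 kb cap
  enter the map. No cross-block partners — a block cartoon, deliberately:
  it reproduces the overlap semantics (neighborhood expansion with a hard
  distance cap), not coalescent reality.
* **Annotations**: clustered intervals (exponential lengths, mean 5 kb, 5
  intervals per cluster) added until realized merged coverage is within
  ±10% relative of the target; ten default tracks span coverages 0.02–0.20.
* **Platforms**: independent Bernoulli memberships (affymetrix 0.4,
  illumina 0.4, hapmap 0.6), with "hapmap" as the catch-all for SNPs drawn
  into no group — mirroring the role of an imputation panel.
* **Planted associations**: labels are drawn without replacement with
  weights $\mathrm{OR}_{target}^{x}$ where $x$ is the SNP's incidence in the
  designated track(s) (exponential tilting). The generator returns the
  *realized* 2×2 table and odds ratio as ground truth, and recovery tests
  compare against the realized value — removing Monte-Carlo ambiguity about
  what "the true OR" of a finite replicate is. 500 associated SNPs (0.8% of
  the default genome) keep association rare, as in real catalogs, while
  leaving enough hits for stable counts.

What passing tests on these genomes shows: the permutation engine counts
exactly, its p-values are calibrated under label exchangeability, planted
effects are recovered without bias, and the joint model separates real from
redundant signal. What they cannot show: robustness to real LD pedigree
structure, annotation error, or catalog ascertainment biases — those have no
generative model here.

## Numerical and design choices

* Rotation offsets are drawn uniformly on $[1, n_{chrom}]$ inclusive, so the
  identity rotation occurs with probability $1/n$ — faithful to drawing
  "between one and the number of SNPs". Offsets are consumed
  chromosome-major (all permutations of chromosome 1, then chromosome 2, …),
  and the drawn offsets are returned with the null object so oracle
  implementations can share the stream.
* $r^2$ comparisons are strict (> threshold). Cross-chromosome LD pairs are
  invalid input, dropped with a warning; pairs naming unknown SNPs are
  dropped with a count.
* A suggestive SNP in LD with a genome-wide-significant SNP is *demoted to
  background* and flagged (`demoted`), rather than removed: removal would
  silently shrink the permutation substrate. Pruning uses direct LD
  partnership only — no transitive closure.
* Chromosome names "chr1" and "1" are canonicalized to one form before any
  matching.
* "Y" and unassigned chromosomes are excluded before status assignment.
* The negative-control track is built by interval subtraction
  (`subtract_tracks`): an intergenic base track minus every genic,
  regulatory and evolutionary annotation; chromatin-state tracks are *not*
  subtracted (the negative set is defined irrespective of epigenetic
  state), and the exclusion list is caller-controlled.
* Degenerate inputs fail loudly: 0/0 odds ratios, empty positive sets,
  constant covariates, non-converged fits, exhausted platform groups are
  all errors naming the offending object.

## Problem sizes used by the test suite

The acceptance checks run, on one CPU, with: oracle equivalence on a
1,002-SNP, 3-chromosome, 5-track toy with 200 shared-offset permutations;
type-I calibration on five 20,001-SNP genomes × 100 uniform label
replicates × 2,000 permutations; planted-OR recovery (targets 1.5, 2, 4) on
five 100,002-SNP genomes × 14 replicates per target with 1,000 permutations
each, judged against each replicate's realized OR; and coefficient/selection
recovery for the joint model at n = 100,000 × 100 replicates. These sizes
were chosen so the whole suite completes in minutes while leaving each
check enough resolution for its stated tolerance (e.g. a binomial 99%
interval around 0.05 needs several hundred replicates to be informative).

## Known limitations

* The LD cartoon has no allele frequencies and no $r^2$ decay with
  distance; within a block all pairs are exchangeable.
* The sampling method's p-values are asymptotic; with very sparse
  annotations (expected null hits near zero) they are reported as `NA`
  rather than invented.
* The permutation p-value is floored at $1/B$; claims below that require
  proportionally more permutations.
* Circular rotation assumes within-chromosome stationarity of the label
  process; gross non-stationarity (e.g. a single mega-locus spanning half a
  chromosome) weakens the null's fidelity.
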