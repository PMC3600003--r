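# circenrich

Are trait-associated SNPs from genome-wide association studies enriched in
particular functional annotations — genic features, conserved elements,
chromatin states? Answering this honestly is harder than counting overlaps:
SNPs and annotations are both clustered along the genome, and every SNP
carries a neighborhood of linkage-disequilibrium (LD) partners. A null model
that samples SNPs uniformly ignores all of that and overstates significance.

`circenrich` is an R package for LD-aware annotation-enrichment analysis
built around a **chromosome-bound circular permutation** null: the vector of
trait-association labels is rotated along the positional SNP order within
each chromosome (wrapping at the end), which preserves the number and
clustering of associated SNPs, the positions of annotations, and the LD
structure, while breaking the label–annotation alignment. It is aimed at
statistical geneticists and functional genomicists who want enrichment odds
ratios with calibrated empirical inference, plus a joint model that weighs
annotations against each other.

## What it computes

For each annotation track, with observed LD-expanded hit count *a* among *n*
associated SNPs and permuted null counts with mean *c̄*:

* odds ratio `OR = a(n − c̄) / ((n − a) c̄)` (>1 enrichment, <1 depletion);
  95% CI from null-count quantiles substituted into the null cell; empirical
  p = fraction of permuted genomes at least as extreme, floored at
  1/(number of permutations); fold enrichment `a/c̄`;
* the same odds ratios under the conventional **platform-weighted sampling
  null** (random background SNP sets matched to genotyping-platform
  composition, Wald CI and p) for comparison;
* a **stepwise-AIC logistic regression** of association status on all
  annotation incidences jointly (platform indicators forced), reporting per
  term the estimate, SE, β-coefficient (estimate/SE) and Wald p, plus
  McFadden and McKelvey–Zavoina pseudo-r², a deviance test against the empty
  model, the combined-annotation odds ratio, and optionally upstream
  distance-to-TSS as a quantitative covariate;
* a **synthetic-genome generator** (clustered SNPs, block LD, clustered
  annotation tracks, platform labels, associations planted at a target odds
  ratio) so the whole stack is testable offline.

## Worked example

```r
library(circenrich)

# a synthetic study: 3 chromosomes x 20,000 SNPs, 10 clustered tracks,
# 500 associated SNPs planted at odds ratio 2 relative to track "feat03"
study <- simulate_study(sim_config(planted_or = c(feat03 = 2), seed = 7))

res <- enrichment_test(study$matrix, study$status,
                       cfg = perm_config(n_permutations = 2000, seed = 7))
res
#> enrichment results (permutation method), 10 annotation(s), 500 associated SNPs
#>  annotation hits null_mean    OR       95% CI       p  fold
#>      feat01   34      32.7 1.040 [0.775-1.59]   0.441 1.040
#>      feat02   44      45.1 0.973  [0.75-1.32]   0.467 0.975
#>      feat03  116      70.6 1.840  [1.45-2.35] <0.0005 1.640
#>      feat04   91      87.6 1.050 [0.847-1.34]   0.358 1.040
#>      feat05  109     107.0 1.030 [0.836-1.29]   0.406 1.020
#>      feat06  145     133.0 1.130 [0.935-1.38]   0.122 1.090
#>      feat07  141     144.0 0.968 [0.812-1.18]   0.378 0.977
#>      feat08  175     159.0 1.150 [0.957-1.38]   0.073 1.100
#>      feat09  180     182.0 0.981 [0.823-1.17]    0.44 0.988
#>      feat10  216     201.0 1.130 [0.945-1.35]   0.095 1.070
```

Only the planted track is called: 116 of 500 associated SNPs hit `feat03`
versus 70.6 expected under rotation, OR 1.84 with 95% CI [1.45, 2.35]; no
rotation among 2,000 was as extreme, so the p-value is reported as the bound
< 5 × 10⁻⁴ (1/2000). The generator's realized ground-truth OR for this
replicate is 1.831, inside the CI. The other nine tracks sit near OR 1 —
the null is calibrated despite their clustering.

```r
mod <- annotation_model(study$matrix, study$status, study$catalog)
mod
#> joint logistic model of trait-association status
#>   selected annotations: feat03
#>   AIC 5761.67 (empty 5788.49); McFadden r2 0.0050, McKelvey-Zavoina r2 0.0152
#>   deviance vs empty: 28.82 on 1 df, p = 7.95e-08
```

The stepwise model keeps exactly the informative track and rejects the nine
redundant ones; the deviance test quantifies the improvement over the
platform-only empty model.

For file-based runs, `run_pipeline()` (or the thin CLI in
`inst/cli/circenrich.R`) reads a SNP table (TSV), LD pairs (PLINK-`.ld`-like
TSV) and BED tracks, assigns significant/suggestive status from P-values
(genome-wide 5e-8, suggestive window up to 5e-5, with LD-based demotion of
suggestive SNPs), runs both nulls on both SNP sets, fits the joint model,
and writes enrichment TSVs, a model TSV and a JSON run manifest.

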