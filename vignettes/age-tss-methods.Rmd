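---
title: "Methods: comparative age-related TSS methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative age-related TSS methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageTSS)
```

This vignette is the package's account of the statistical procedures it
implements, the assumptions behind them, the parameters that matter, and
the design decisions taken where more than one reasonable choice existed.

## The measurement model

RRBS reports, per sample and per CpG site, the number of reads supporting
the methylated and the unmethylated state. The package treats the read
counts as authoritative (the percentage column of the coverage dialect is
validated but never used in computation) and works throughout on two
scales:

* the **beta scale**, `beta = meth / total`, bounded in [0, 1] and directly
  interpretable as a methylation proportion; and
* the **M scale**, `M = log2(beta / (1 - beta))`, which approximately
  stabilizes the variance of proportions and is the scale on which linear
  models are fitted.

Because region betas arrive as ratios (not counts), the M transform clamps
beta into `[epsilon, 1 - epsilon]` with `epsilon = 0.01` by default rather
than offsetting counts. The clamp bounds the leverage of fully
(un)methylated regions: without it a region at beta = 0 maps to minus
infinity. `epsilon` is configurable; values in 0.005–0.05 change little
because the bimodal mass sits close to, but not at, the boundaries.

### Coordinates

Input coverage files and annotations are 1-based inclusive. All internal
interval arithmetic is 0-based half-open; the converters at the IO boundary
are the only places a ±1 appears. CpG records on opposite strands of one
dinucleotide are *not* collapsed by default — `collapse_strands()` exposes
the choice (greedy left-to-right pairing of adjacent positions) for
pipelines that prefer dinucleotide resolution.

## Region building

One region per gene is constructed in four steps, each a separate
function so intermediate results are testable:

1. **TSS extraction**: the 5' end of every protein-coding transcript
   (annotation start on `+`, end on `-`).
2. **Ambiguity filter**: a transcript is discarded when a TSS of a
   *different* gene on the same chromosome lies closer than `min_sep =
   2000` bp (strict inequality, symmetric — both genes lose the
   transcripts involved). Alternative TSS of one gene never conflict; the
   rule exists to make the CpG-to-gene assignment unique, and a gene
   cannot be ambiguous with itself.
3. **Selection**: each surviving TSS is extended to the closed interval
   `[tss - 1000, tss + 1000]` (2001 bp; the symmetric window that includes
   the TSS base itself) and, per gene, the region with the largest number
   of CpGs measured in the all-samples-covered site set is chosen. Ties are
   broken deterministically: smallest start coordinate, then smallest
   transcript id. Whether the window is 2001 or 2000 bp is immaterial in
   practice (a CpG on the boundary base is rare) but the choice is encoded
   once and documented so it is auditable.
4. **Aggregation and filtering**: the region beta per sample is the
   pooled-count ratio `sum(meth) / sum(total)`, algebraically identical to
   the coverage-weighted mean of per-CpG betas (an identity the test suite
   asserts to 1e-12). Regions are kept when the per-sample *mean* coverage
   per CpG (`sum(total) / n_cpgs`) reaches `min_cov = 5` in every sample
   and the betas vary across samples. A per-CpG minimum is available via
   `coverage_mode = "per_cpg"`; the mean is the default because the region
   value itself is an aggregate, so an aggregate coverage criterion is the
   matching notion. Regions with an undefined beta (zero pooled reads in
   some sample) are always removed.

## The age model

Each region's M-value row is regressed on age in years by ordinary least
squares. With `n` samples, the per-region residual variance `s2` has
`d = n - 2` degrees of freedom and the age coefficient has unscaled
variance `v11 = 1 / sum((age - mean(age))^2)`.

Thousands of regions share information through an empirical-Bayes prior on
the residual variance: `s2 ~ s02 * chi2_d / d` given a true variance drawn
from a scaled inverse chi-square with `d0` prior df. The hyperparameters
are estimated by moment matching on `e = log(s2) - digamma(d/2) +
log(d/2)`: `d0` solves `trigamma(d0/2) = var(e) - trigamma(d/2)` (Newton
inversion of the trigamma function), and `s02 = exp(mean(e) +
digamma(d0/2) - log(d0/2))`. When the spread of log variances does not
exceed what sampling alone produces, `d0` is infinite and every region
receives the common variance `s02`. Regions with `s2 = 0` (perfect fits)
are excluded from estimation — their log is undefined — but still receive
a shrunken variance. The moderated statistic

```
s2_post = (d0 * s02 + d * s2) / (d0 + d)
t       = beta_hat / sqrt(s2_post * v11),   df = d + d0
```

reduces exactly to the OLS t when `d0 = 0` and to a normal score when
`d0` is infinite. P-values are two-sided, adjusted by the
Benjamini–Hochberg step-up, and regions with adjusted p below
`alpha = 0.05` (strict) are called ageTSS with direction `gain` or `loss`
from the sign of the age coefficient. No threshold other than the BH 0.05
convention is assumed; `alpha` is a parameter. Age enters in years as a
real number (20 months = 1.667); no covariates are modelled.

Cohort ordination uses classical multidimensional scaling (principal
coordinates) of the Euclidean distances between sample columns, computed
on the 1000 most variable regions — variance is taken across the whole
cohort, blind to age, so the selection cannot bias the ordination toward
the age effect. Negative eigenvalues are truncated to zero, standard
principal-coordinates practice.

## Cross-species comparison

Two species are compared only over genes with a high-confidence one2one
orthologue, and only where both species' regions survived the coverage and
variability filters (inner join). Per species, a gene's methylation is the
unweighted mean across samples of its region betas — samples are the
replication unit, so they carry equal weight. Conservation is the Pearson
correlation of those means with the usual t-based p-value. Bimodal classes
use strict thresholds (`hypo < 0.05`, `hyper > 0.95`); a value exactly at
a threshold is intermediate. Species-specifically hypomethylated sets are
the (hypo, hyper) and (hyper, hypo) corners of the class table. Age
effects are compared by pairing the per-region age coefficients and
counting pairs significant in both species.

## Enrichment

Over-representation uses the hypergeometric upper tail `P[X >= k]` with an
*explicit background universe*: `N` background genes, `K` of them in the
set, `n` query genes, `k` in both. Query and set members outside the
universe are dropped before testing (dropped query ids are counted), and
sets with no background member are skipped; BH adjustment runs across the
tested sets. The two natural backgrounds in this pipeline are all covered
genes (for ageTSS queries) and the joined orthologue set (for
species-specific queries); `run_comparison()` uses the latter
automatically. A web-service enrichment tool was deliberately not wrapped:
an in-repo hypergeometric test is transparent and reproducible, at the
price of not being numerically identical to any particular service's
variant.

## Expression integration

Raw single-cell counts of all cells from one tissue (or stage) of one
embryo are summed into a pseudobulk column, so embryos are the biological
replicates; tissues with fewer than two embryos are flagged and excluded
from testing. Columns are normalized to CP10K + 1
(`count / column_total * 1e4 + 1`).

Two questions are asked of these values:

* **Does sperm promoter methylation predict embryo expression?** Genes are
  stratified by their sperm methylation class (hyper vs hypo, from the
  same species), each gene contributes its mean normalized expression
  across a tissue's embryos, and the two strata are compared by a Wilcoxon
  rank-sum test (exact enumeration when both strata have at most 10 values
  and no ties; otherwise the normal approximation with tie and continuity
  correction). The per-gene summary is the mean, not the median, for
  determinism with tiny replicate counts.
* **Which genes differ between species at a stage?** Per gene, the log2
  ratio of mean CP10K+1 between species, a Welch t-test on the
  log2(CP10K+1) replicate values, BH within the stage, and tiers
  `*` (< 0.01), `**` (< 1e-5), `***` (< 1e-10) on the adjusted p. The
  Welch-on-pseudobulk statistic is a deliberate, documented simplification
  relative to negative-binomial DE machinery: it is self-contained,
  transparent, and adequate when each species contributes a handful of
  replicates — but see the df floor below.

"Relative expression" for clustering is the per-gene z-score of stage-mean
log2 values; genes are ordered by id before agglomerative clustering
(Euclidean distance, complete linkage) so the dendrogram is deterministic
under ties, and constant genes are centered to zero with a warning.

### The small-replicate df floor

A Welch test with `r` replicates per side has at most `2r - 2` degrees of
freedom. With `r = 4`, even an arbitrarily large fold change cannot push
the p-value much below ~1e-4, so after multiplicity adjustment over
thousands of genes a genuine 4-fold change may not reach adjusted
p < 0.01 *regardless of effect size*. This is a property of the statistic,
not of the data. Consequences drawn in this package: the coupled-cohort
checks of fold-change recovery use six embryos per tissue (well within the
replication of published embryo single-cell compendia), and the
demonstration of pathway-level differential expression restricts testing
to a focused gene panel — which is also how a pathway-directed analysis
proceeds in practice. Users applying `stage_de()` genome-wide with 2–4
replicates should expect conservative adjusted p-values.

## The synthetic cohort generator

`simulate_methylomes()` emulates the statistical structure the pipeline is
built to detect; its defaults are the cohort conditions the package is
designed around:

* 13,914 orthologous genes; 15 samples aged 1.7–12.5 years in species A
  (4 young, 6 prime-adult, 5 old) and 73 samples aged 25–51 in species B;
* bimodal class proportions `p_hypo = 0.76`, `p_hyper = 0.063`, the rest
  intermediate, with class distributions Beta(0.5, 30), Beta(30, 0.5) and
  Beta(2, 2);
* planted linear age drift on the M scale (`0.08` M units/year) in 204/13914
  of species-A genes (85% gains) and 27/13718 of species-B genes (4% gains),
  with disjoint planted sets between species;
* a cross-species mean-beta correlation target of 0.611 and 132 / 197
  planted discordant (species-specifically hypomethylated) genes;
* negative-binomial per-CpG coverage (mean 30, size 5 — RRBS-like
  overdispersion), ~12 CpGs per region (Poisson, floor 3), per-CpG M-scale
  jitter (sd 0.25) and per-sample biological noise (sd 0.1 M units).

Three generator design choices deserve explanation:

* **Classes are definitional.** Each class draws its latent region beta
  from the class Beta distribution *truncated to the class window*, with a
  0.01 guard band separating the intermediate class from the 5%/95%
  thresholds and a 0.002 floor keeping extreme latents away from exactly
  0/1. Without truncation a "hypo" gene could straddle the threshold and a
  numerically-zero gene would emit all-zero counts and fall to the
  variability filter — in both cases the truth table would silently
  disagree with what the pipeline can observe. Planted discordant genes
  sit well inside the extreme windows for the same reason. The trade-off
  is explicit: the generator does not exercise threshold-straddling
  regions, so classification behaviour *at* the boundary is covered by
  direct unit tests instead.
* **The correlation dial is calibrated in closed form.** Between-species
  correlation of latent mean betas is controlled by sharing the class
  label for a fraction `1 - q` of genes and redrawing it otherwise
  (never producing an extreme-opposite pair by chance — full discordance
  is exclusively planted, so planted counts are exactly recoverable).
  `q` is solved from the truncated-Beta mixture moments so that the latent
  correlation equals the configured target; no simulation feedback is
  involved.
* **Age effects are planted on intermediate-baseline genes.** On the beta
  scale a fully (un)methylated region cannot drift — the boundary
  saturates any slope — so drift planted there would be undetectable by
  construction; partially methylated regions are where age-related change
  is observable and reported. Planted slopes are centered at the cohort
  mean age, so a gene's mean beta remains its latent class value.

`simulate_embryo_counts()` couples expression to the methylome truth:
negative-binomial counts around a shared log-normal baseline, scaled by
`2^meth_effect_log2` (default −1: halved) for genes hypermethylated in
that species' sperm, log-normal per-cell library factors, and planted
cross-species fold changes (default 30 genes, 4-fold, one stage each)
drawn from the top baseline-expression quartile — a fold change on a
near-silent gene is unobservable after CP10K+1.

What the generator does **not** emulate: read-level artefacts (bisulfite
conversion error, mapping bias, PCR duplicates), spatially correlated
methylation along a chromosome, CpG-island structure, covariate structure
(batch, cell composition), cell-type heterogeneity within a tissue, and
zero-inflation beyond the negative binomial. Passing tests therefore show
that the *statistical machinery* is correct and well calibrated under the
generative model — not that real libraries are free of the artefacts the
upstream QC/alignment steps (out of scope here) must handle.

## Problem sizes of the packaged checks

The test suite validates the region builder against a brute-force
implementation on 200 random small annotations (≤ 50 genes each, planted
2-kb conflicts and multi-TSS genes); error control on 10 null cohorts of
5000 regions × 15 samples; power/FDR/direction recovery on three cohorts
with 200 planted effects among 5000 regions; cross-species recovery at
10,000 orthologue pairs; and the coupled expression cohort at 1200 genes ×
7 tissues × 6 embryos × 12 cells per species. These sizes were chosen so
the full suite exercises cohort-scale behaviour while remaining quick to
run; the acceptance script runs the genome-scale defaults (13,914 genes).

## Known limitations

* The moderated model assumes exchangeable residual variances across
  regions after the M transform; strong mean-variance structure (e.g.
  boundary regions with clamped betas) is only partially absorbed by the
  prior.
* The 2-kb ambiguity rule discards genuinely bidirectional promoters.
* Cross-species comparability inherits whatever biases the supplied
  orthologue map carries; the package filters but does not infer
  orthology.
* The Welch pseudobulk DE is conservative at small replicate counts (df
  floor above) and ignores count-level dispersion sharing across genes.
* `pearson_correlation()` reports `p = 0` below double precision rather
  than a symbolic "< 2.2e-16".
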