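---
title: "Discovering shared ceRNA networks across tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering shared ceRNA networks across tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long non-coding RNAs and pseudogenes can act as miRNA *sponges*: their
transcripts carry miRNA response elements, so when such a transcript is
abundant it sequesters part of the shared miRNA pool and indirectly raises the
expression of mRNAs targeted by the same miRNAs. A sponge, an mRNA and a
shared miRNA form a competing-endogenous-RNA (ceRNA) triplet. `cernet`
implements a multi-cohort screen for such triplets: per-cohort differential
expression, per-cohort triplet inference, intersection across cohorts, and
downstream prognostic and gene-set screens. Because the interesting biology is
what replicates across related tumor types, the unit of inference is the
triplet that survives in *every* cohort.

```{r setup}
library(cernet)
```

## The screening model, stage by stage

### Differential expression

Raw counts are normalised with TMM (trimmed mean of M-values): per-gene log2
ratios against a reference sample are computed on library-size-normalised
counts, trimmed 30% on M and 5% on A, and averaged with inverse delta-method
variance weights; the factors are rescaled to geometric mean 1. A pure
sequencing-depth difference therefore yields factors of 1 — depth is carried by
the *effective library size* (column total times factor) inside the log-CPM
transform, `log2((count + 0.5) / (eff.lib + 1) * 1e6)`. The 0.5/+1 offsets are
the standard CPM convention. Features with log-CPM below 1 in strictly more
than half the samples are removed; the same rule is applied to genes and
miRNAs.

Per-feature two-group models (tumor minus normal) are moderated with the
empirical-Bayes variance shrinkage: residual variances are pooled toward a
scaled-inverse-chi-square prior whose degrees of freedom `d0` and scale `s0^2`
are estimated by matching moments of `log(s^2)` (digamma/trigamma identities);
the moderated t uses the posterior variance `(d0 s0^2 + d s^2)/(d0 + d)` with
`d0 + d` degrees of freedom, capped at the pooled residual df when `d0` is
estimated infinite. We deliberately do not use precision weights on the
mean-variance trend: the transform is only a bridge to a roughly homoskedastic
scale, a trend-free moderated t keeps the module self-contained, and the test
suite verifies it against an independent reference implementation to numerical
precision. Features are called `up`/`down` at |logFC| > 1 and
Benjamini–Hochberg FDR < 0.01.

### Triplet inference

For every differential sponge (lncRNA or pseudogene) and differential mRNA,
three gates are applied, in order:

1. **Shared-miRNA over-representation.** With `N` miRNAs in the interaction
   map, `n` targeting the sponge, `K` targeting the mRNA and `m` shared, the
   p-value is the hypergeometric upper tail `P(X >= m)`. BH across all tested
   pairs, gate FDR < 0.05. We use the `P(X >= m)` convention (sum of the pmf
   from `m` upward): under the inclusive-limit variant `P(X > m)` a pair
   sharing every available miRNA could never be significant, which contradicts
   the purpose of an over-representation test; the inclusive variant remains
   available via `as_printed = TRUE`.
2. **Positive co-expression.** Pearson correlation of the pair on tumor-sample
   log-CPM; keep `r > 0.4`, strictly. Correlations use tumor samples only:
   normals carry no sponge-driven signal of interest and would dilute the
   estimate; the comparison with normals is the business of the DE stage.
3. **Multiple sensitivity correlation.** `mscor = cor(g1, g2) -
   pcor(g1, g2 | M)`, the drop in pair correlation after partialling out the
   shared miRNA set `M` (with one miRNA this is the classical sensitivity
   correlation). The partial correlation is computed by residualising both
   genes on an intercept plus the miRNA profiles; a rank check rejects
   collinear control sets by name. Significance is assessed against a
   simulated null: pairs are stratified by correlation bin (width 0.1, centers
   at odd multiples of 0.05) and control-set size `i`; per stratum, 1000
   datasets are drawn at the observed sample size with `g1, g2` bivariate
   normal at the bin-center correlation and `i` independent standard-normal
   miRNAs, and `empirical_p = (1 + #[null >= obs]) / (1000 + 1)` — the add-one
   estimator avoids zero p-values. BH across pairs, gate adjusted p < 0.05.

Surviving pairs emit one triplet per shared miRNA used in the control set.
Shared miRNAs are *not* required to be differentially expressed: the
hypergeometric test is about the wiring of the interaction map, not about
miRNA abundance shifts, and the null model of the mscor stage already
conditions on the observed miRNA profiles.

### Cross-cohort integration

Each triplet is collapsed to the canonical key
`"<sponge>_<mRNA>_<miRNA>"` (ids must not contain underscores; enforced on
construction and on parsing). After within-cohort deduplication, a one-way
frequency table over keys is built and keys with frequency equal to
`required_count` — by default the number of cohorts — form the shared network.
At full frequency this is provably the intersection of the per-cohort key
sets, and the test suite checks that equivalence against a brute-force
intersection oracle. Venn-style sharing counts per feature role and a
Cytoscape-importable edge table accompany the network.

### Downstream screens

For each shared-network feature and cohort, tumor samples are split at the
median expression (ties to the low group, making the split deterministic),
Kaplan–Meier curves are estimated, and the logrank (Mantel–Haenszel) test
compares the groups; the statistic is chi-square with 1 df. The hazard ratio
is the ratio of observed/expected event counts `(O_high/E_high)/(O_low/E_low)`
— the estimator that belongs to the logrank accumulation; no Cox model is fit
anywhere. The reported `direction` names the expression group with the
*better* survival (the group whose O/E ratio is smaller); this labelling
choice is deliberate and documented in the output schema, since "high/low"
annotations in survival tables are otherwise ambiguous. A feature is
prognostic if significant (p < 0.05) in at least one cohort. Gene-set
over-representation of the shared-network mRNAs reuses the same
hypergeometric kernel over user-supplied GMT collections; reproducing
ontology-specific annotations would require external databases and is out of
scope.

## The synthetic-study generator

Real multi-cohort tumor data cannot ship with a package, so `cernet` includes
a generator that emulates the statistical structure the screen relies on,
plus the planted ground truth needed for recovery tests:

* miRNA log2 abundances are Gaussian per sample around per-miRNA baselines
  (`N(12, 1)`), giving log-normal abundances;
* each gene's log2 mean decreases linearly — slope `repression_strength` — in
  the standardized abundance of every miRNA that targets it in the map. A
  planted sponge–mRNA pair is wired to exactly `shared_mre_count` common
  miRNAs and nothing else, so the pair shares a latent component and is
  positively correlated, the mechanism the Pearson and mscor stages detect;
* planted differential features get a `±de_logfc` shift in tumors; a fraction
  of decoys get shifts in random directions, and a fraction is simulated
  near zero abundance to exercise the low-expression filter;
* counts are negative-binomial (the standard bulk RNA-seq model; a log link
  keeps effects multiplicative) with log-uniform library-size multipliers in
  `libsize_range` so that TMM has real work to do;
* tumor survival times are exponential with proportional hazards,
  log-hazard `hazard_beta` per standardized unit of each planted prognostic
  feature (the mRNAs of the first three shared triplets and the anchor miRNAs
  of the first two, alternating risk direction), with independent exponential
  censoring tuned to `censor_rate`.

Everything is deterministic given the seed: each cohort, the map and the gene
sets draw from independent streams derived from the master seed, and a study
written twice is byte-identical.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| cohorts; samples | 5; 60 tumor + 10 normal | five-cohort layout at desk scale; unbalanced groups mimic tumor/normal archives |
| genes; miRNAs | 200 mRNA + 60 lncRNA + 40 pseudogene; 100 miRNA | large enough for meaningful BH corrections, small enough for minutes-scale runs |
| `repression_strength` | 0.35 | with 6 shared miRNAs this puts planted-pair correlations near 0.6–0.75, comfortably above the 0.4 gate, while keeping the extra expression variance small enough that a ±2 log2 shift remains estimable against the |logFC| > 1 threshold |
| `shared_mre_count` | 6 | a realistic shared-MRE count for a strong sponge pair |
| `nb_dispersion` | 0.1 | biological coefficient of variation ≈ 0.32, typical of bulk tumor cohorts |
| `de_logfc` | 2 | a clear two-fold-change planting against the |logFC| > 1 call threshold |
| `libsize_range` | (0.5, 2) | four-fold depth spread, routine in archival data |
| `hazard_beta` | 1.2 | strong but not deterministic prognostic signal at n = 60 with 30% censoring |
| `censor_rate` | 0.3 | common follow-up loss level |
| `background_density` | 0.05 | ~5 regulators per decoy gene under 100 miRNAs, enough chance sharing to make the hypergeometric screen non-trivial |

What the generator does **not** emulate: read-level sampling, isoform
structure, batch effects, copy-number or methylation confounding, and
correlated miRNA families. Passing the recovery tests therefore demonstrates
that the pipeline's statistics behave as designed under its own model
assumptions — not that the thresholds are optimal for any particular real
cohort collection.

## Numerical and design choices

* Hypergeometric tails are computed from the exact pmf sum; the test suite
  re-derives them by exhaustively enumerating all `C(N, n)` draws for every
  universe up to N = 12.
* The partial correlation uses QR residualisation; an independent
  precision-matrix route (inverting the `(2+i)`-dimensional correlation
  matrix) agrees to 1e-10 on random instances, and the identity
  `mscor = cor - pcor` holds exactly by construction.
* Empirical null p-values use the add-one estimator, so the attainable range
  is `[1/(B+1), 1]` for `B` null draws; with the default `B = 1000` and BH
  across a handful of pairs the smallest adjusted values are ~1e-3.
* Median-split ties go to the low group; a constant expression vector is a
  degenerate split and an error, and the prognostic screen skips (with a
  warning) features that are absent, constant, or whose logrank variance is
  zero.
* Duplicate sample columns on read are dropped keep-first with a warning;
  negative or fractional counts are parse errors that name the feature and
  line.
* All stage thresholds (1, 0.01, 0.05, 0.4, 0.05, 0.05) are configurable in
  `pipeline_config()` but default to the canonical screen.

## Problem sizes used by the checks

The bundled tests and the acceptance script run the full pipeline on the
default 5-cohort study (≈ 25 s end to end), calibrate the mscor null on a
no-planting study sized to yield roughly 200 candidate pairs, and estimate the
logrank null rejection rate from 1000 replicates at n = 60. These sizes were
chosen so the whole suite completes in about a minute while keeping each
Monte-Carlo interval informative.

## Known limitations

* The mscor null conditions on a binned correlation rather than each pair's
  exact estimate; at extreme correlations (|r| > 0.95) the bin-center
  approximation coarsens.
* The O/E hazard ratio is a crude estimator when one group's expected count
  is near zero; such rows carry `NA` and are excluded from direction calls.
* The one-way frequency rule tests exact equality with `required_count`,
  mirroring the frequency-table definition; "at least k of K" semantics, if
  wanted, can be had by lowering `required_count` and unioning.
* With very small cohorts (a dozen tumors) the mscor stage loses power
  rapidly — residualising on six noisy miRNA profiles with twelve samples
  leaves little signal; the defaults (60 tumors) avoid that regime.
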