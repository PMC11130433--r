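---
title: "Longitudinal trait derivation and transient-QTL mapping with tempoqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal trait derivation and transient-QTL mapping with tempoqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempoqtl)
```

## The problem

High-throughput phenotyping platforms image every plant of a diversity
panel every day, yielding a trait value per plant per day after planting
(DAP). Mapping those daily traits one day at a time turns a genome-wide
association study into a *longitudinal* GWAS: a marker can be significant
during one developmental window and silent elsewhere — a transient QTL.
Detecting such windows matters because an allele whose effect acts early
(say, on growth rate under cold) leaves a persistent mark on attained
size, so an early transient signal predicts the endpoint phenotype.

tempoqtl implements the full chain for a replicated inbred panel grown
under a staged temperature schedule: trait derivation and QC from raw
pixel measurements, per-day broad-sense heritability, temporal profile
clustering and ideotype classification, a multi-locus mixed-model (MLMM)
association engine run per trait per day, transient-track assembly, and
a candidate-gene window scan. A synthetic-data generator with recorded
ground truth makes every step testable by parameter recovery.

## Trait derivation and quality control

Raw inputs are long-format tables of pixel measurements: one top view and
two side views of projected area, height and convex-hull pixels, daily
water added, and endpoint fresh weight. Derivation proceeds in a fixed
order; permuting input records never changes the result.

1. **Composite area** is the sum of the three view pixel counts times a
   zoom-level scale factor (`composite_area()`); the zoom changed at 19
   and 40 DAP in the protocol we model, so scale factors are per-period
   configuration inputs.
2. **Germination** is the earliest day with positive top-view area;
   the accession-level date is the replicate mean. A plant that is zero
   for five consecutive days after germinating is called dead (the
   operational rule behind the 46-DAP exclusion). Accessions keep their
   place only if at least two plants established (`exclude_failed()`).
3. **Gross artifact removal**: a value more than 40 raw median absolute
   deviations from the median is removed, never imputed. The fence is
   applied per trait per day *across plants*, where measurements are
   homogeneous enough that 40 MAD (about 27 standard deviations under
   normality) flags only segmentation failures. Applied along a growth
   series instead, the MAD spans orders of magnitude and the rule would
   be vacuous. Zeros from not-yet-germinated plants are structural, not
   measurements, and are masked before the fence is computed. A zero-MAD
   day is left unfiltered (the rule is undefined there).
4. **Smoothing**: each plant's series is replaced by loess fitted values
   (span 0.5, degree 2 by default). Fitted values, not raw values, are
   the phenotype downstream.
5. **Aggregation**: the accession value is the replicate median
   (heritability uses the pre-median replicate values).

Biomass is calibrated by ordinary least squares of endpoint fresh weight
on area at 51 DAP (areas later than that are unreliable in the modeled
protocol because plants overlap the camera frame); predictions are
floored at zero. WUE at day *t* is area divided by cumulative water
through *t*, missing (not infinite) while no water has been recorded.
RGR between consecutive days is the difference of the replicate
log-mean areas, reported at the later day.

### Smoothing bandwidth versus temporal localization

Loess with span 0.5 over a ~50-day series averages over roughly a
±12-day neighborhood. That is fine for denoising an endpoint analysis,
but it *smears* a sharp effect onset backwards: a QTL that switches on at
20 DAP becomes weakly visible in the smoothed phenotype from about 12
DAP. Any analysis that asks *when* an effect starts must keep the
smoothing bandwidth narrower than the windows it hopes to resolve. The
transient-recovery experiments in this package therefore run the trait
pipeline with span 0.25 (a ±6-day neighborhood); the package default
stays 0.5, which is the stabler choice when localization is not the
question. This tradeoff is inherent to smoothing, not an artifact of the
implementation.

## Heritability

At each trait and day the one-way random-effects model
`Y = mu + genotype + error` is fitted to replicate values of accessions
with full replication, and broad-sense heritability is
`H2 = sigma2_genotype / (sigma2_genotype + sigma2_error)`. Two paths are
implemented — REML via `lme4::lmer` (the default) and the balanced-design
ANOVA method of moments `(MSB - MSW) / r` with negative estimates clipped
at zero — and they agree to numerical precision on balanced data, which
the tests assert. H2 recovery is checked by simulation: with equal
variance components (true H2 = 0.5) at 300 accessions x 3 replicates the
mean estimate over 100 replications falls in [0.45, 0.55].

## Temporal profiles, clusters, ideotypes

Accession-by-day matrices over DAP 12-56 are clustered with Ward's
method on Euclidean distances (`hclust` method `ward.D2`, the Ward
variant appropriate for unsquared distances) and cut at `k` clusters
(default 7, with `silhouette_curve()` as a diagnostic since no selection
rule is prescribed). Accessions with incomplete profiles are dropped with
a warning; rows are pre-sorted by accession id so input order cannot
change tie resolution. Alongside each cluster's mean profile a
"clustergram-style" PCA-weighted mean is reported: members are weighted
by the rank of their score on the first principal component of the
profile matrix.

Daily cross-sections are converted to percentiles by
`100 * (rank - 1) / (n - 1)` with mid-ranks for ties (all-tied days give
50). Ideotype-positive accessions have a window-mean WUE percentile in
the top 10% *and* a height:biomass-ratio percentile in the bottom 5%;
ideotype-negative is the mirror image. The windows are 15-31 DAP (early,
cold phase) and 39-56 DAP (late, after the temperature step-up).
Selection is monotone: tightening either threshold can only shrink the
sets.

## The multi-locus mixed model

The association engine fits `y = X beta + u + e` with
`u ~ N(0, sigma2_g K)` and `e ~ N(0, sigma2_e I)`, where `K` is the
Astle-Balding kinship `(1/m) sum_i (x_i - 2 p_i)(x_i - 2 p_i)' /
(2 p_i (1 - p_i))` computed from post-imputation dosages, and `X`
contains the intercept plus the first three genotype principal
components. Variance components are profiled over
`delta = sigma2_e / sigma2_g` on a log grid over [1e-5, 1e5] after a
single eigendecomposition of `K`; the pseudo-heritability is
`1 / (1 + delta)`.

The forward search alternates: re-estimate the variance components under
the current cofactors, scan all remaining markers by generalized least
squares with the components held fixed (the standard approximate scan;
an exact per-marker REML scan exists behind `exact = TRUE` for oracle
tests), and add the most significant marker as a fixed cofactor. Ties
are broken by genome order. The search stops when the remaining
pseudo-heritability falls to or below 0.01 (a numerical stand-in for
"reaches zero"), when 20 cofactors have been added, or when no marker
can be added. One subtlety: the stopping statistic measures the
heritable variance *remaining under the current model*, and at the null
model a mono- or oligogenic signal is invisible to the kinship term
(pseudo-heritability near zero even though a strong QTL exists). The
first forward step is therefore always attempted; the rule applies from
the first cofactor onwards. Backward steps are not taken: the procedure
we model is described as pure forward addition.

Model selection follows the two standard criteria. The
multiple-Bonferroni (mBonf) model is the largest model on the path whose
every cofactor p-value is at or below `alpha / m` with `m` the number of
markers tested (no effective-number-of-tests correction — the modeled
protocol applies plain Bonferroni). The extended-BIC model minimizes
`-2 logLik(ML) + k log(n) + 2 gamma log C(m, k)` with `gamma = 1`. The
high-confidence set is their union, tiered `stringent` (mBonf) versus
`lower` (extended-BIC only) — the two-asterisk versus one-asterisk
convention in allele-trajectory displays.

Scan correctness is pinned to an independent oracle that builds
`Sigma = sigma2_g K + sigma2_e I` explicitly and inverts it per marker:
p-values agree to 1e-8. Familywise error of mBonf selection is checked
on 200 null simulations (rate must sit in the [1%, 9%] binomial band
around 5%), and power on a planted marker explaining ~22% of variance
(first cofactor in at least 90% of runs).

Phenotypes enter each per-day fit Box-Cox transformed when a
Shapiro-Wilk test rejects normality at 0.01 (lambda maximizing the
profile likelihood over [-2, 2] in steps of 0.01, the log branch at
lambda = 0); the decision is logged per fit.

## Transient tracks, pleiotropy, allele trajectories

The per-(trait, day) high-confidence hits form a significance tensor.
For each marker-trait pair the significant days are grouped into maximal
consecutive runs (strict consecutiveness by default; a gap tolerance
exists because daily fits are noisy). A track is transient when runs are
separated by a non-significant day or the track ends before the final
analyzed day. Note the asymmetry built into growth: a *rate* effect
confined to an early window permanently shifts attained size, so its
track legitimately extends past the window's end — the recovery criteria
accept significance through the end of the run while requiring silence
*before* the window. Pleiotropic markers are those hit for two or more
traits. `allele_effect_series()` reports per-day class means and Welch
t-tests between the homozygous allele classes (suppressed, with a flag,
below 3 accessions per class), with GWAS tier tags per day.

## The synthetic-data generator

The generator emulates the study design the analysis assumes, with every
stochastic component on its own labelled seed stream (adding a component
never perturbs another's draws):

* **Genotypes**: inbred accessions (dosages 0/2) in `n_subpops`
  subpopulations under the Balding-Nichols model — ancestral frequencies
  Uniform(0.1, 0.9), subpopulation frequencies
  Beta(p(1-F)/F, (1-p)(1-F)/F) at `fst = 0.2` by default — with markers
  placed at strictly increasing positions on 5 chromosomes. Markers are
  independent within subpopulations: there is no local LD, so candidate
  windows contain no "shoulder" signal and structure is the only marker
  correlation.
* **Growth**: a discrete logistic recursion
  `A[t+1] = A[t] + r_t A[t](1 - A[t]/Amax)` from 1% of `Amax` at the
  accession's germination day (drawn from 5-9 DAP). The daily rate is
  scaled 0.35 / 0.7 / 1.0 in the 15, 24 and 32 degree phases (days 1-31,
  32-38, 39-56): no growth-rate-versus-temperature law is printed in the
  protocol we model, so the multipliers are configurable with these
  defaults. The base rate 0.18/day and `Amax` 50,000 px leave the panel
  at ~70% of the asymptote at 56 DAP — still growing at harvest, which
  is what lets early rate effects remain visible in endpoint size.
* **QTL**: each planted QTL adds `effect_size x dosage/2` to the growth
  rate, the asymptote, or the trait value itself, only on days inside
  its window.
* **Polygenic background**: one standardized draw per accession from
  `N(0, K_realized)`, scaled by the population mean curve and by
  `sqrt(h2/(1-h2))` times the noise coefficient of variation, so the
  realized plant-level heritability equals `polygenic_h2` exactly in
  expectation (verified by simulation: mean 0.497 over 60 seeds at a
  target of 0.5, with the noise floor off).
* **Noise**: per plant per day, coefficient of variation 0.1 relative to
  the mean curve, plus an absolute 25 px floor (segmentation noise does
  not shrink with the plant — this is what makes heritability *rise*
  through early growth), and an optional late-run noise multiplier
  emulating leaf overlap after ~43 DAP (off by default; switching it on
  reproduces the rise-then-fall heritability shape).
* **Watering**: daily water replaces evaporation plus area-proportional
  transpiration, capped at the 250 g saturation deficit of the fixed
  1192 g target-mass protocol (342 g carrier + 250 g water + 600 g pot;
  the protocol deliberately ignores plant mass, and so does the model).
* **Failures and artifacts**: a configured fraction of plants never
  germinates (all-zero top view); a configured fraction of measured
  cells is multiplied by 50 and recorded in the truth object.

What the generator does *not* emulate: linkage disequilibrium decay,
heterozygosity, genotype-by-environment interaction beyond the shared
temperature multipliers, spatial or conveyor-position effects, and
image segmentation itself (pixel tables are emitted directly). Passing
recovery tests therefore says the *methods* behave as designed under
these statistical conditions, not that real image-derived data meet
those conditions.

## Design choices in the recovery experiments

Two experiment-level choices deserve explicit justification.

* The transient-recovery runs set `polygenic_h2 = 0`. The polygenic
  background is by construction a function of the marker genotypes, so
  with it on, a structured marker is *genuinely* associated with the
  phenotype on every day (correlations near 0.4 arise through
  subpopulation structure alone). "No significance before the window"
  is then not a false-positive statement. With the background off the
  planted QTL is the only genetic signal and window localization is
  well-defined. Familywise-error behavior under a null phenotype is
  tested separately.
* Those runs also use loess span 0.25, for the bandwidth reason above.

## Numerical choices

* REML search on log-delta over [1e-5, 1e5] with `optimize` (tolerance
  1e-8), endpoints checked explicitly; eigenvalues of K clipped at zero.
* Markers collinear with the covariates get p = 1 and a flag; a marker
  whose residual norm falls below 1e-10 of its whitened norm counts as
  collinear.
* Negative variance-component estimates are clipped at zero; H2 of a
  degenerate all-zero fit is reported as 0.
* Dosage imputation uses the marker mean of observed calls; the MAF
  filter is strict (`MAF > 0.05` kept) and zero-variance markers are
  dropped regardless.
* Candidate windows are closed intervals: a gene touching
  `pos +/- 15000` exactly is included; GFF3 coordinates are 1-based
  inclusive throughout; strand is ignored for inclusion and reported for
  context.
* PCA signs are fixed by making each component's largest-magnitude
  loading positive.
* Percentile convention `(rank - 1)/(n - 1)` with mid-ranks; all-tied
  cross-sections give 50 everywhere.

## Problem sizes

The test suite and the acceptance script run the method at desk scale,
chosen so each statistical check has the power it needs and no more:
panels of 50-200 accessions with 60-500 markers, 200 null GWAS runs for
familywise error, 100 power runs, 20 (tests) or 10 (script) full
end-to-end transient-recovery runs at 200 accessions x 500 markers x 45
analyzed days, 100 heritability replications at 300 x 3, and 1000 random
window-scan configurations. The real study this emulates was two orders
of magnitude larger in markers; nothing in the implementation depends on
these sizes.

## Known limitations

* The approximate scan holds variance components fixed within a step;
  exact per-marker REML is available but quadratic-times-slower.
* extBIC's ML likelihoods re-optimize delta per path model; on very long
  paths this is the slowest part of a fit.
* RGR is defined from replicate log-means, so it exists only at the
  accession level and has no per-plant replicate structure for
  heritability.
* With `n_subpops > 3` the three-PC default undercorrects structure,
  exactly as it would in a real panel; `n_pcs` is configurable.
* The clustering k is a configuration input; the silhouette curve is a
  diagnostic, not an automatic selector.
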