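---
title: "Methods: genotype associations with CGM-derived glycemia in family cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype associations with CGM-derived glycemia in family cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycovar)
```

## The scientific problem

The T allele of rs7903146, an intronic variant of *TCF7L2*, raises type 2
diabetes risk and has been linked to enhanced hepatic glucose production.
Continuous glucose monitoring (CGM) samples interstitial glucose every five
minutes for several days, so it can resolve *when* during the day a genetic
effect on glycemia acts — in particular in the night, when circulating
glucose derives almost entirely from endogenous (hepatic) production — and
whether the variant alters glycemic *variability* rather than the mean.

glycovar implements the full analysis chain for such a candidate-SNP CGM
study in a family cohort:

1. per-participant CGM summaries (glycemia and variability),
2. covariate-adjusted comparison of genotype groups (CC vs combined CT/TT)
   with family-cluster-robust inference and Monte Carlo permutation
   p-values,
3. mediation of the genotype effect by body composition as percent of
   effect explained,
4. a synthetic-cohort generator with known ground truth, used to validate
   every stage.

## CGM summary statistics

A monitoring record nominally spans five days at five-minute sampling. The
first and the last calendar day (sensor insertion and removal) are the least
accurate and are discarded, leaving a 72-hour analysis window
(`trim_to_analysis_days()`). Per participant we compute:

**Glycemia** — arithmetic means of valid samples pooled across analysis
days, over three clock windows: the full day, nocturnal 03:00–06:00, and
diurnal 06:00–24:00. Windows are half-open `[start, end)`. Note the hours
00:00–03:00 belong to neither window; we reproduce that convention rather
than extend the nocturnal window, so "nocturnal" isolates the hours in
which participants are almost surely asleep and fasting.

**Variability** —

* `sd_24h`: the sample SD (n−1) of all valid samples of the 72-h record.
* `conga` (CONGA 4): for every observation with a partner exactly 4 h
  earlier on the grid, form the difference; CONGA is the sample SD of those
  differences. An intraday measure.
* `modd`: the mean absolute difference of glucose values at exactly the
  same grid clock time on consecutive days, pooled over all consecutive-day
  pairs. An interday measure.
* `range`: max − min of valid samples.

### Numerical and convention choices

* **n−1 denominator everywhere.** The defining literature for CONGA and the
  24-h SD does not state the denominator; n−1 matches the default of every
  mainstream statistics package, and at 864 samples the distinction is
  negligible (relative difference < 0.06%).
* **Pooled versus per-day.** The 24-h SD and the range are computed once
  over the pooled 72-h record by default; averaging per-day values first is
  available behind `per_day = TRUE`. Pooled is better behaved under
  missingness and treats the record the way CONGA and MODD do.
* **MODD with three analysis days** pools the slot-wise absolute
  differences of both consecutive pairs (day 1→2 and 2→3) into a single
  mean rather than averaging two daily MODDs. With complete coverage the
  two definitions coincide; under missingness pooling weights every
  observed pair equally instead of up-weighting pairs from sparse days.
* **Missing data.** Samples are explicit `NA`s on the grid. A window mean
  requires at least 70% of its grid slots valid (configurable
  `min_coverage`); CONGA and MODD simply skip pairs with a missing member —
  no interpolation. "Exactly the same time of day" means the same grid slot
  after snapping; sub-interval jitter is absorbed by snapping timestamps to
  the nearest slot (tolerance half an interval).
* **Day boundary** is calendar midnight of the sensor's local timestamps.
  First/last-day exclusion removes calendar days, not 24-h offsets from the
  (unknown) insertion time.
* Physiologic bounds: values outside (0, 40) mmol/L are rejected at parse
  time.

## Genotype-group comparison

Participants are dichotomised as CC versus CT/TT (T-allele carriers); TT
homozygotes are too rare at minor-allele frequencies near 0.3 to analyse
separately. For each outcome we fit OLS of the (optionally log-transformed)
outcome on the carrier indicator plus covariates — by default age, sex and
offspring/partner status, the design covariates of a family-based cohort.

**Cluster-robust inference.** Siblings share environment and genotype, so
rows are not independent. The variance of the coefficient vector uses the
one-way cluster sandwich grouped by family with the small-sample factor
`c = [G/(G−1)]·[(N−1)/(N−k)]` and a t reference with `G − 1` degrees of
freedom (G families, N participants, k coefficients). This is the exact
behaviour of the `vce(cluster)` convention in mainstream econometric and
survey software, chosen so results are comparable to the way such studies
are conventionally analysed. With singleton clusters it reduces to HC1
(a tested invariant).

**Adjusted (geometric) means.** Group means are evaluated at the sample
means of the covariate design columns; on the log scale the mean and its CI
are exponentiated, yielding geometric means. Fasting insulin is
log-transformed by default (right-skewed); the set of log-scale outcomes is
configuration, not hard-coded, because skewness conventions differ between
cohorts.

**Permutation p-values.** Model-based p-values at N ≈ 235 with clustered
data lean on asymptotics, so each comparison also gets a Monte Carlo
permutation p-value (default 1000 permutations): the carrier labels are
shuffled and the model refitted, and the p-value is the add-one estimator
`(1 + #{|β*| ≥ |β|})/(m + 1)`, which can never report an impossible zero.

*Permutation unit.* Genotype is correlated within families, so permuting
individual labels would break exchangeability under the clustered model.
The default therefore shuffles the observed per-cluster label *patterns*
among clusters of equal size: every member of a cluster moves together, the
marginal genotype counts are preserved exactly, and for singleton clusters
the scheme reduces to ordinary label permutation. Individual-level
shuffling remains available (`unit = "individual"`) for sensitivity checks.

**Hardy-Weinberg check.** `hwe_test()` is the standard 1-df chi-square
goodness-of-fit against expected genotype counts at the observed allele
frequency; a monomorphic sample returns p = 1 by convention.

**Multiple testing.** Nine outcomes are compared at a fixed two-sided 0.05
without multiplicity correction, mirroring common practice in hypothesis-
generating candidate-SNP studies. This is a known limitation: at nine
outcomes the family-wise error rate at the nominal 0.05 is roughly 0.37
under independence.

## Mediation as percent of effect explained

If carriers differ in body composition, and body composition raises
glucose, part of the genotype–glucose association is *mediated*. On the
complete-case subset (outcome, covariates and all mediators observed) the
package fits the base model and the base+mediators model **on identical
rows** and reports

percent mediated = 100 · (β_unadjusted − β_adjusted) / β_unadjusted.

Before interpreting this as mediation the package tests group×mediator
multiplicative interaction (mediator mean-centred) for every mediator; a
significant interaction flags the result as not interpretable as a simple
mediated fraction (the difference-in-coefficients measure assumes effect
homogeneity). Values outside [0, 100] — suppression — are flagged, never
truncated. The quantity is invariant to rescaling the outcome (tested).

Causal-counterfactual mediation machinery (natural direct/indirect
effects, bootstrap CIs) is deliberately out of scope; the percent-explained
summary is the quantity this study design reports.

## The synthetic cohort generator

No individual-level data from such cohorts are publicly deposited, so the
package ships a generator that reproduces the statistical *structure* the
analysis assumes, with known ground truth. It is first-class, tested code —
the validation of every analysis stage rests on it.

**Genotypes and families.** A configurable fraction of participants
(default 0.4) forms two-person sibling clusters; each sibling draws one
allele from each of two shared parents whose alleles are Bernoulli(p),
p = 0.28 by default (a common European T-allele frequency, giving ≈ 48%
carriers). Marginally the genotype distribution is exactly Hardy-Weinberg;
within families dosages correlate at r = 1/2. Singletons draw two alleles
independently.

**Phenotypes.** Age ~ N(64.7, 5.9²) years; 50% female; 62.6% offspring.
Weight ~ N(76.7, 12.3²) kg and percent body fat ~ N(30.3, 8.3²) for
non-carriers, with carrier shifts of +2.5 kg and +1.5 points — the
magnitudes such middle-aged non-diabetic cohorts report. The BMI
eligibility band [19, 33] kg/m² is enforced by resampling *height* given
weight, so the configured genotype→weight effect stays exactly recoverable
(truncating weight itself would bias it).

**Traces.** Each trace is

* a smooth circadian baseline: a 24-h raised cosine with nadir 4.45 mmol/L
  at 04:00 and amplitude 1.0 mmol/L, plus Gaussian meal excursions
  (amplitude 1.5 mmol/L, SD 35 min) at 08:00, 13:00 and 19:00 — values
  chosen so the non-carrier window means land near 4.5 (nocturnal) and 5.4
  (diurnal) mmol/L, typical of normoglycemic adults;
* a genotype shift for carriers with a raised-cosine nocturnal shape over
  00:00–07:00, normalized so that the carrier mean over the 03:00–06:00
  window rises by exactly `direct_effect` — this makes recovery tests
  unbiased by construction and reproduces the signature of a nocturnal
  effect with near-coincident midday curves;
* a whole-day shift of `mediator_to_glucose` mmol/L per SD of the
  standardized body-composition composite `(z_weight + z_pbf)/√2` — the
  mediated pathway;
* a family-shared random intercept (SD 0.1 mmol/L). Cohort studies rarely
  report within-family outcome correlation, so this is a guessable knob
  exposed as configuration, not asserted truth;
* AR(1) sensor noise between consecutive 5-min samples (autocorrelation
  0.7, marginal SD 0.5 mmol/L) — CGM noise is strongly autocorrelated at
  5-minute spacing;
* 2% of samples missing completely at random. Real sensor dropout is
  bursty; uniform missingness is the simplest mechanism consistent with
  the metrics' skip-pairs handling and is a stated simplification.

The default effect split (`direct_effect` 0.124, `mediator_to_glucose`
0.245) implies a total nocturnal effect of 0.19 mmol/L of which ≈ 35% is
mediated — the magnitude regime of interest.
`config_with_mediated_fraction()` solves those two fields for any desired
total effect and mediated fraction.

**What the generator does *not* emulate** — and hence what passing tests do
not establish about real data: sensor calibration drift against capillary
glucose, bursty dropout, diet- and exercise-driven day-to-day variation,
age/sex effects on glucose, and non-Gaussian tails. Recovery tests validate
the *pipeline*, not the biology.

## Validation design and problem sizes

The test suite validates each metric against independent brute-force
references (two-pass SD, timestamp-join CONGA/MODD, sort-based range) on
random series up to length 2000 with up to 30% missingness, checks
hand-computed golden values (CONGA lag-2 of [5,6,5,7,6] = 0.5774; MODD of
the two-day toy = 0.5; HWE chi-square of (30,40,30) = 4.0), and verifies
shift invariance and scale equivariance of all seven statistics.

Statistical calibration runs at the study's own design point, n = 235:

* permutation type-I error over 500 replicate null cohorts (200
  permutations each) must lie in [0.03, 0.07] at nominal 0.05;
* the adjusted β averages to the configured 0.19 mmol/L over 200
  replicates, and robust 95% CIs cover truth 93–97% of the time over 1000
  replicate cohorts of sibling pairs (a binomial proportion needs tighter
  Monte Carlo error than a mean, hence the larger replicate count);
* percent mediated averages within ±5 points of the configured 35% over
  50 replicate cohorts of n = 5000;
* two pipeline runs with one seed are byte-identical (CSV MD5s and config
  hash).

The replicate counts above are the package's chosen validation sizes: large
enough that Monte Carlo error is well below each acceptance band, small
enough to run routinely.

## Known limitations

* The difference-in-coefficients mediation measure is biased under
  exposure–mediator interaction or non-linearity; the package screens for
  interaction but cannot rule out non-linear mediation.
* Percent mediated computed from *rounded, printed* coefficients can
  disagree with the value computed from unrounded estimates — e.g. printed
  coefficients 0.17 and 0.11 give 35.3%, while the unrounded fit they were
  rounded from can legitimately print 34.6%. The package always computes
  from unrounded estimates.
* Cluster-robust t(G−1) inference is approximate for few or very
  unbalanced clusters; the permutation p-value is the fallback and both are
  always reported side by side.
* Window means use no within-window time weighting; with ≥ 70% coverage on
  a 5-minute grid the bias is negligible, but the threshold is a
  convention, not a derived quantity.
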