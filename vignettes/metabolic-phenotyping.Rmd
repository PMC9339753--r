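---
title: "From oxygen traces to metabolic phenotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From oxygen traces to metabolic phenotypes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respscope)
```

## The measurement model

Intermittent-flow respirometry estimates a fish's oxygen uptake rate
(ṀO₂, mg O₂ h⁻¹) from the decline of oxygen concentration in a sealed
chamber. The system cycles through loops of three phases — flush (the
chamber is re-oxygenated), wait (a short lag so the decline is linear
when measurement starts), and a sealed measurement phase. The default
protocol is 180 s flush / 30 s wait / 210 s measure at 18 °C, repeated
for at least 121 loops (an overnight trial of just over 14 h). Phase
intervals are half-open `[start, end)`; a sample at an exact boundary
belongs to the next phase. Time zero is the start of the first wait
phase: the animal is chased to exhaustion and placed in the chamber
*during* the wait, so the first measurement phase is linear, usable,
and captures the highest rates.

For each measurement phase we fit ordinary least squares of oxygen
concentration on time. The slope `b` (mg O₂ L⁻¹ s⁻¹) converts to a
whole-animal rate through the effective water volume:

ṀO₂ = −b · 3600 · (V_chamber − m/1000),

with chamber volume in litres and body mass `m` in grams (the fish is
assumed neutrally dense, 1 g ml⁻¹; respirometry practice varies on the
volume convention, so it is stated here explicitly and can be
reconciled against any particular system).

**Background respiration.** Microbial activity in the system consumes
oxygen too. It is measured in the empty chamber immediately before and
after the trial; each background measurement is itself an OLS fit, and
is retained only when that fit's R² exceeds 0.1 (a noisy near-zero
background carries no usable signal — a strict gate read literally from
standard practice). With both endpoints retained the background rate is
interpolated linearly across the trial; with one it is held constant;
with none it is zero with a warning. The fitted background, evaluated
at each phase's midpoint, is subtracted from that phase's raw ṀO₂.
Negative corrected values are floored at zero with a warning rather
than dropped — dropping them would bias the standard metabolic rate
upward, flooring at worst biases single phases slightly up.

**Quality control.** Any phase whose oxygen-on-time fit has R² < 0.90
is removed before the summary statistics; phases with undefined R²
(zero oxygen variance) also fail. Both gates (0.1 and 0.90), and the
SMR decile below, are arguments throughout, and every threshold used is
recorded in the outputs.

**Summary statistics.** From the QC-passed, background-corrected ṀO₂
series: SMR (standard metabolic rate) is the mean of the lowest 10 % of
values, where the count is rounded half-up with a floor of one (121
phases → the 12 lowest; the decile makes SMR robust to the right-skewed
activity distribution); MMR (maximum metabolic rate) is the global
maximum, with ties resolved to the earliest phase; AAS = MMR − SMR and
FAS = MMR/SMR hold exactly by construction. Fish with fewer than 10
usable phases (configurable) are flagged and excluded from statistics
rather than summarised badly. Whether the "lowest 10 %" should be taken
before or after flooring negatives is ambiguous in common usage; this
package floors first, so a heavily over-corrected trial degrades
visibly (warnings plus a cluster of zeros) instead of silently.

## Mass normalisation

Metabolic rates scale allometrically with body mass, so group
comparisons use residuals: both mass and each measure are
log-transformed and one pooled OLS of log(measure) on log(mass) is
fitted across the whole cohort per measure. Pooling is deliberate —
separate per-group fits would absorb exactly the group differences the
analysis is meant to test. The default log base is 10 (conventional in
metabolic scaling). The base rescales residuals by a constant and
cancels from every downstream F statistic and p-value (tested), but
contrast *magnitudes* are reported in log units, so the base is carried
in the output metadata. Fish with non-positive values (an AAS of zero)
cannot be log-transformed and are excluded from that measure's fit with
a warning.

## Resource-use grouping from δ¹³C

In lakes, lower muscle δ¹³C indicates greater reliance on pelagic
(open-water) carbon. Fish are clustered on δ¹³C alone — one dimension —
by k-means with 25 random starts, keeping the best solution by
within-cluster sum of squares. In one dimension the optimal k-partition
is contiguous in sorted order, so an exact dynamic-programming solution
exists; the test suite verifies that 25 starts attain that exact
optimum on every tested instance (n ≤ 200). Centers are reported in
increasing order and labels attach to center order, never to run-order,
so results are invariant to permuting the input. With k = 3 the
clusters are labelled HIGH/MID/LOW pelagic resource use by increasing
δ¹³C; with k = 2, HIGH/LOW. Crossing capture habitat with the k = 2
labels yields four habitat-by-resource groups; groups smaller than
`min_group_n = 2` are excluded with a recorded reason (a group of one
fish supports no contrast). Clustering runs on all fish jointly, not
per habitat — the joint scale is what makes "high pelagic reliance"
mean the same thing in both habitats.

## The inferential layer

Each mass-independent measure is modelled as
`residual ~ sex + group` by OLS with sum-to-zero factor coding.
Variance is partitioned with type-2 sums of squares when no interaction
is present and type-3 when one is (the covariate screen below);
type-3 tests are contrast-dependent and sum-to-zero coding is the
convention under which they test marginal means. Group differences are
Tukey-adjusted pairwise contrasts of estimated marginal means, which
average predictions over the other factors' levels with *equal*
weights (not observed frequencies); p-values come from the studentized
range distribution on the residual degrees of freedom, and with two
levels reduce exactly to the ordinary t-test. Habitat δ¹³C separation
is additionally tested by the Mann-Whitney U (midranks; exact
enumeration p when n₁·n₂ ≤ 400 without ties, otherwise the
tie-corrected normal approximation; both U₁ and the min-U convention
are reported). Optional morphology covariates (principal-component
scores) are screened in a type-3 model including covariate × habitat
interactions; covariates whose terms are all non-significant at
α = 0.05 are dropped and the reduced model is refitted. α = 0.05
throughout, with no correction across the four responses — four
related readouts of one phenotype, reported side by side.

## The synthetic-trial generator

Every stage is testable by parameter recovery because the generator
knows its truth. It emulates:

- a cohort of 22 littoral + 29 pelagic fish, masses 27.7 ± 9.7 g and
  26.9 ± 9.3 g;
- latent SMR drawn on the log10 scale around an allometric law
  (3.0 mg O₂ h⁻¹ at 27 g, exponent 0.8, residual SD 0.04 log units),
  with a habitat effect of +0.062 log units for pelagic fish (about
  15 %) and +0.03 for males; MMR likewise around 12 mg O₂ h⁻¹ with no
  habitat effect, floored at 1.2 × SMR;
- a post-chase trajectory starting at MMR and decaying exponentially to
  SMR (τ = 3600 s), punctuated by Poisson activity bursts (2 h⁻¹,
  lognormal magnitudes, 120 s decay) truncated at MMR — the burst
  process is what makes "lowest 10 %" a meaningful SMR estimator;
- background respiration drifting linearly from 0.1 to 0.3 mg O₂ h⁻¹
  across the trial, plus sealed 600 s empty-chamber measurements before
  and after;
- Gaussian sensor noise (SD 0.02 mg O₂ L⁻¹ per 1 Hz sample) and a
  small AR(1) temperature jitter around 18 °C (never used to correct
  rates — the study design is single-temperature);
- chambers size-matched to each fish (0.5 L at the 27 g reference,
  scaling linearly with mass), as in real systems — a fixed chamber
  would make small fish fail the linearity gate wholesale;
- littoral δ¹³C from a two-component mixture (−24.7 and −23.3 ‰,
  SD 0.5 ‰, 45 % weight on the lower, more pelagic-reliant mode) and
  pelagic δ¹³C from a single component (−24.96 ± 0.61 ‰), matching the
  bimodal-littoral / unimodal-pelagic pattern of lake fish; δ¹⁵N
  defaults (12.8/13.2 ± 0.5 ‰) are plausible perch values and play no
  role downstream of I/O.

Everything is reproducible from a single integer seed; the same seed
yields byte-identical cohorts and traces.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: specific dynamic action (digestion), diel
activity cycles, hypoxia feedback on uptake, sensor drift within a
trial, chamber mixing lags, and any temperature dependence. Burst-rate
and magnitude defaults are plausible-by-construction, not calibrated to
any deposited trajectory; they are configuration, not claims.

## Numerical choices and degenerate inputs

- Phase R² is the squared Pearson correlation; a constant-oxygen phase
  has undefined R², slope 0, and fails QC.
- Segments with fewer than 3 points are skipped with a warning.
- The SMR decile count is `max(1, floor(0.10 · n + 0.5))` — round
  half-up, floor one.
- k-means with k equal to the number of (distinct) points returns
  singleton clusters exactly; fewer distinct values than k is an error,
  not a silent merge.
- Rank-deficient ANOVA designs raise an error naming the aliased
  coefficients; rows with missing model variables are dropped as
  complete cases and counted in the result.
- A constant response yields F = 0 for every term rather than 0/0.
- One physical limitation is worth stating: in a noiseless post-chase
  trial, no single decay constant lets the pipeline recover SMR and MMR
  both exactly — the first phase *averages* the decay, so any finite τ
  under-reads MMR, while an instant decay hides it entirely. The
  noiseless recovery tests therefore isolate the two estimators with
  τ → 0 and τ → ∞ respectively (both recover to ≤ 0.1 %); at the
  default τ = 3600 s the MMR under-read is ~2–3 %, which is exactly the
  situation of a real chase protocol.

## Problem sizes used in the tests

The suite simulates full-length 121-loop trials where the protocol
matters (recovery on 50 fish; single-trial properties) and shorter
20–40-loop trials where it does not (identities, equivariance). The
calibration checks run the cohort-level generative model without traces
(400 null and 100 alternative cohorts), which is the level at which the
type-I/power properties of the ANOVA are defined. The full suite runs
in well under a minute on one core.
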