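# respscope

Intermittent-flow respirometry analysis and metabolic phenotyping for
comparative ecophysiology: from raw overnight oxygen traces to
standard/maximum metabolic rate, aerobic scope, mass-independent
residuals, stable-isotope resource-use groups, and the group-comparison
statistics — with a synthetic-trial generator so every stage is
verifiable by parameter recovery.

## The problem

Within-species ecotypes (for example littoral vs pelagic lake fish)
can differ not just in morphology and diet but in whole-animal
energetics. Quantifying that requires a chain of estimation steps, each
with conventions that materially change the result:

1. **ṀO₂ per measurement phase.** An intermittent-flow system cycles
   flush (180 s) / wait (30 s) / sealed measurement (210 s) loops for
   ≥ 121 loops (~14 h). Each sealed phase gives an OLS slope *b* of
   oxygen on time, converted to a whole-animal rate by
   ṀO₂ = −*b* · 3600 · (V<sub>chamber</sub> − m/1000) in mg O₂ h⁻¹.
2. **Background correction.** Microbial respiration, measured in the
   empty chamber before and after the trial (each retained only if its
   own fit has R² > 0.1), is interpolated linearly across the trial and
   subtracted at each phase midpoint.
3. **Quality control.** Phases with R² < 0.90 are removed.
4. **Summary.** SMR = mean of the lowest 10 % of ṀO₂ values (round
   half-up count; 12 of 121), MMR = global maximum (the trial starts
   post-chase, at maximal rates), AAS = MMR − SMR, FAS = MMR/SMR.
5. **Mass normalisation.** Residuals of log₁₀(measure) on log₁₀(mass),
   one pooled regression per measure.
6. **Grouping.** One-dimensional k-means (25 starts) on δ¹³C: k = 3
   resource-use classes, and k = 2 crossed with capture habitat (groups
   with n < 2 excluded).
7. **Inference.** `residual ~ sex + group` with type-2 sums of squares
   (type-3 when an interaction is present, under sum-to-zero coding),
   Tukey-adjusted pairwise contrasts of estimated marginal means,
   Mann-Whitney U for the δ¹³C habitat separation, and a screen that
   drops non-significant morphology covariates (PC scores) and their
   habitat interactions.

`respscope` implements the whole chain as composable functions with
every threshold exposed, and ships a generator of synthetic trials with
known ground truth (post-chase exponential decay from MMR to SMR,
Poisson activity bursts, drifting background, sensor noise, bimodal
littoral vs unimodal pelagic δ¹³C) so the pipeline's recovery error and
the calibration of its tests are measurable facts, not hopes.

## Worked example

```r
library(respscope)

cfg   <- sim_config(n_littoral = 10, n_pelagic = 10)  # full 121-loop trials
study <- simulate_study(cfg, seed = 7)
res   <- run_pipeline(study, seed = 7)

head(res$processed$summaries[, c("fish_id","smr","mmr","aas","fas","n_phases_used")], 4)
#>   fish_id      smr      mmr       aas      fas n_phases_used
#> 1    F001 3.245105 13.70761 10.462504 4.224088           121
#> 2    F002 5.413588 18.16832 12.754731 3.356059           121
#> 3    F003 5.255892 17.57881 12.322914 3.344590           121
#> 4    F004 4.133213 12.03945  7.906233 2.912854           121

res$models$habitat$resid_smr$anova
#> ANOVA (type 2 SS), n = 20
#>      term      F df1 df2         p
#> 1     sex  2.388   1  17 1.407e-01
#> 2 habitat 35.524   1  17 1.551e-05
#> Model: F(2,17) = 18.96, p = 4.695e-05, adj R2 = 0.65

res$models$habitat$resid_smr$contrasts
#>             contrast    estimate      se df        p_adj
#> 1 LITTORAL - PELAGIC -0.08177361 0.01372 17 1.551183e-05
```

Reading the output: each fish's 121 phases all passed QC; SMR/MMR are
in mg O₂ h⁻¹. The habitat model tests the mass-independent SMR
residual controlling for sex; the contrast says littoral fish sit
0.082 log₁₀ units (~17 %) below pelagic fish in mass-independent SMR —
the generator's configured habitat effect (0.062 plus sampling noise),
recovered through the entire trace-level pipeline.

Real data enter through `read_trace_csv()` (native headered CSV, or
vendor exports via a column map and a YAML protocol config),
`read_cohort_table()`, then `process_study()` →
`build_analysis_table()` → `compare_groups()`; results are written as
deterministic TSVs by `write_results()`.

## Layout

- `R/` — protocol/trace/cohort I-O, the synthetic generator
  (`sim_config`, `simulate_study`), the ṀO₂ core (`process_trace` and
  its parts), mass normalisation, δ¹³C grouping, the stats layer, and
  the pipeline drivers.
- `tests/testthat/` — unit, property and acceptance tests, with
  independent oracles (closed-form OLS, exact dynamic-programming 1-D
  k-means, Mann-Whitney enumeration, Monte-Carlo studentized range).
- `vignettes/metabolic-phenotyping.Rmd` — the models, assumptions,
  defaults, and design choices in full.
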