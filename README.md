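# powersppb

Muscle-power variants of the Short Physical Performance Battery (SPPB) and
a harness for comparing them as predictors of adverse outcomes in
mobility-limited older adults.

## What it does and for whom

The SPPB sums three 0–4 component scores — hierarchical standing balance,
4-m usual-pace gait, and the five-repetition sit-to-stand (5STS) — into a
0–12 composite (higher = better lower-limb function). Because muscle power
declines earlier and faster with age than strength, a power-based
re-scoring of the chair-stand component may track prognosis better. This
package, aimed at geriatrics and epidemiology researchers, implements:

- **Sit-to-stand power** from anthropometrics and 5STS time:

  AMP (W) = 0.9 · m · g · (0.5·h − h_chair) / ((t / r) · 0.5)

  with body mass m (kg), stature h (m), chair height h_chair (m), time t
  (s) over r repetitions, plus the normalized variants RMP = AMP/m (W/kg),
  ALMP = AMP/h² (W/m²), and SMP = AMP/ALM (W/kg appendicular lean mass).
- **Five composite indexes** — the traditional SPPBt and SPPBamp, SPPBrmp,
  SPPBalmp, SPPBsmp, in which the chair score is replaced by sex-specific
  power quartiles (lowest quartile → 1, highest → 4, 0 reserved for
  "unable").
- **The comparison harness**: per-sex Kaplan–Meier curves and adjusted Cox
  proportional-hazards models (per-point hazard ratios for mobility
  disability, hospitalization, death; Efron ties; listwise deletion), AIC /
  ΔAIC ranking with a lowest-AIC (LAIC) flag and a common-sample guard, and
  covariate-adjusted fixed-horizon ROC with AUC bands (0.7–0.8 acceptable,
  0.8–0.9 excellent, >0.9 outstanding).
- **A synthetic cohort generator** (396 men / 1026 women by default, SPPB
  3–9, Weibull proportional-hazards event times calibrated to 44.5% / 32.4%
  / 4.3% two-year incidences) so the entire pipeline runs end-to-end
  without access to trial data.

## Worked example

```r
library(powersppb)

compute_amp(body_mass = 70, stature = 1.60, chair_height = 0.45, t5sts = 19.2)
#> [1] 112.6617      # watts; RMP = 112.66 / 70 = 1.61 W/kg

rep_ <- run_pipeline(cohort_cfg = cohort_config(n_men = 120, n_women = 260),
                     seed = 7)
rep_$aic$women.disability
#>             index      aic delta_aic is_laic                band
#> SPPBt       SPPBt 1209.742  0.000000    TRUE   equally plausible
#> SPPBamp   SPPBamp 1214.293  4.551236   FALSE moderate difference
#> SPPBrmp   SPPBrmp 1214.424  4.681776   FALSE moderate difference
#> SPPBalmp SPPBalmp 1216.645  6.903011   FALSE moderate difference
#> SPPBsmp   SPPBsmp 1216.409  6.667319   FALSE moderate difference
```

The pipeline simulates (or accepts) a cohort, scores power and all five
indexes, applies the eligibility filter (missing-5STS exclusion, SPPB 3–9),
fits unadjusted and adjusted Cox models per sex × outcome × index — the
adjusted hazard ratio is the multiplicative risk change per index point,
e.g. HR 0.67 (95% CI 0.59–0.75) per point for women's disability above —
ranks the five models by ΔAIC within each stratum, and computes the
adjusted 730-day AUC grid. In this simulated cohort the hazards are driven
by the traditional index, so SPPBt is flagged LAIC; drive them with
`event_config(index = "sppb_rmp")` to see the ranking move. The methods
vignette (`vignettes/methods.Rmd`) documents the model, parameter defaults,
and design decisions.

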