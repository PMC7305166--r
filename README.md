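# ipfpfis

Neuro-fuzzy prediction of infrapatellar fat pad (IPFP) volume from serum
adipokine profiles, with swarm-based variable selection.

## What this package is for

The IPFP is the fat body behind the patellar tendon; its volume (mm³) is a
marker of knee osteoarthritis onset and progression, normally measured by
MRI segmentation. This package implements a serum-based prediction pipeline
for researchers in osteoarthritis biomarker modelling:

* **Design space** — 48 candidate predictors per subject: the three main
  osteoarthritis risk factors (age, gender, BMI), nine serum markers
  (adiponectin HMW/LMW, adipsin, chemerin, leptin, visfatin, CRP, IL-8,
  MCP-1), and their 36 pairwise ratios, C(9,2).
* **PSOBVS** — particle-swarm wrapper variable selection over subset sizes
  1–48 (2⁴⁸−1 ≈ 2.81×10¹⁴ subsets per group; C(48,5) = 1,712,304 at size 5),
  with a 0.7·train + 0.3·test weighted RMSE fitness under k = 4
  cross-validation, Monte-Carlo resplit repetition for stability, and AIC
  (`n·ln(SSE/n) + 2p`) to pick the winning size.
* **ANFIS-FCM** — a first-order Takagi–Sugeno fuzzy system: rule base induced
  by fuzzy c-means clustering, Gaussian premises, linear consequents, hybrid
  learning (global least squares + guarded gradient descent). Output is the
  firing-strength-weighted average of rule consequents.
* **Evaluation** — R, scatter index (RMSE/mean), MAPE, RMSRE, relative-error
  fractions, SDFE with the 95% uncertainty band (±1.96·SDFE), and
  Taylor-diagram coordinates.
* **Studies** — BMI/gender stratification, the five-variable "model #5" per
  group, a 26-model ablation grid, gender-separation and inverse-ratio
  comparisons, leakage-guarded external validation, and export of trained
  models as JSON + human-readable pseudocode.

The original cohorts are access-restricted, so a seeded synthetic-cohort
generator with the same statistical structure (log-normal markers, a planted
0.58 adiponectin HMW–LMW correlation, BMI mixture straddling the 30 kg/m²
obesity cut, and a known linear outcome in gender, BMI, age and adipsin/CRP)
makes every stage testable end to end.

## Worked example

```r
library(ipfpfis)

co <- generate_cohort(cohort_spec(n_subjects = 1000, seed = 1))
fm <- build_features(co)          # 48-column design
sel <- select_subsets(fm, sizes = 2:6, swarm_config(mc_repeats = 3, seed = 1))
print(sel)
```

```
PSOBVS selection result
  M= 2  AIC=   4817.07  fitness= 3371.7204  {gender, bmi}
  M= 3  AIC=   4758.17  fitness= 2918.2102  {gender, bmi, adipsin/CRP}
  M= 4  AIC=   4669.31  fitness= 2522.8072  {age, gender, bmi, adipsin/CRP}
  M= 5  AIC=   4669.17  fitness= 2514.9578  {age, gender, bmi, adipsin/CRP, leptin/visfatin}
  M= 6  AIC=   4673.86  fitness= 2507.1322  {age, gender, bmi, adiponectin_LMW/MCP1, adipsin/CRP, leptin/visfatin}
  winner: M=5 (lowest AIC)
```

Every candidate from size 4 upwards contains all four planted generating
variables (gender, BMI, age, adipsin/CRP). On this particular seed the
held-out AIC at size 5 edges out size 4 by 0.14 — differences under ~2 are
statistically a tie, and across 20 replicate cohorts the AIC minimum lands
at the true size 4 in 95% of runs (see `scripts/acceptance.R` below);
in-search fitness, by contrast, always improves with size, which is exactly
why the held-out AIC makes the call.

```r
model <- anfis_fcm(fm, features = sel$winner$subset, n_rules = 2,
                   cfg = train_config(seed = 1))
metrics <- compute_metrics(fm$target, predict(model, fm))
print(metrics)
#> metric_set (n=1000): R=0.9122  SI=0.0784  MAPE=6.59%  RMSRE=0.0837
#>   relative error: <10%: 78.0%  <15%: 93.3%
```

With noise sd 2500 mm³ planted on volumes around 30,000 mm³, an R near 0.91
and MAPE near 7% is the ceiling any correct model can reach on this cohort —
the residual is the irreducible noise, which is the point of the planted
design.

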