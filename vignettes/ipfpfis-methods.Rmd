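---
title: "Neuro-fuzzy prediction of infrapatellar fat pad volume: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuro-fuzzy prediction of infrapatellar fat pad volume: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipfpfis)
```

## The problem

The infrapatellar fat pad (IPFP) is the adipose body behind the patellar
tendon; its volume tracks knee osteoarthritis onset and progression, but
measuring it requires MRI and segmentation. This package implements a
serum-based alternative: predict IPFP volume (mm³) from the three main
osteoarthritis risk factors (age, gender, BMI), nine serum adipokine and
inflammatory-marker concentrations (adiponectin HMW and LMW, adipsin,
chemerin, leptin, visfatin, CRP, IL-8, MCP-1), and all 36 pairwise ratios of
those markers — 48 candidate predictors in total.

Two machine-learning components carry the analysis:

1. **PSOBVS** — particle-swarm wrapper variable selection over the subset
   lattice of the 48 features, with Monte-Carlo resplit repetition for
   stability and AIC to choose the model size. Exhaustive search is
   impossible: sizes 1–48 contain $2^{48}-1 \approx 2.81\times 10^{14}$
   subsets per cohort group.
2. **ANFIS-FCM** — a first-order Takagi–Sugeno fuzzy system whose rule base
   is induced by fuzzy c-means clustering and refined by hybrid learning;
   this is the volume predictor.

The original clinical tables are access-restricted, so the package ships a
seeded synthetic-cohort generator with the same statistical structure; every
stage is tested against planted ground truth.

## The synthetic cohort

`cohort_spec()` / `generate_cohort()` emulate an osteoarthritis progression
cohort: by default 678 subjects with an expected 290 female / 388 male split,
age uniform on 45–79 y, and BMI from an equal-weight two-component normal
mixture (means 26 and 34 kg/m², sd 2.5 and 3) so the obese (BMI ≥ 30) and
non-obese strata are roughly balanced, near 341/337. Biomarkers are
log-normal — strictly positive and right-skewed, as serum assays are — with a
coefficient of variation of about 0.5; the location parameters are
placeholders at plausible serum magnitudes, since the source per-marker
distributions are not published. The two adiponectin isoforms share a latent
Gaussian factor giving a log-scale correlation of 0.58, the strongest
marker–marker correlation reported for such panels; all other markers are
independent.

The planted outcome is linear:

$$\mathrm{IPFP} = \beta_0 + \beta_g\,\mathbb{1}[\text{male}] + \beta_b\,\mathrm{BMI}
  + \beta_a\,\mathrm{age} + \beta_r\,\frac{\text{adipsin}}{\text{CRP}} + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2).$$

Defaults: $\beta_0 = 20000$, $\beta_g = 9000$ (males larger, as observed
anatomically), $\beta_b = 450$ per kg/m², $\beta_a = -150$ per year,
$\beta_r = 1500$ per ratio unit, $\sigma = 2500$ mm³. These were chosen so
that each generating variable is individually *strong* — its contribution
spread is at least ~1100 mm³ against the 2500 mm³ noise — because the
selection tests ask whether a strong planted signal is recovered; with a
marginal effect the question changes from "does the search work" to "is the
effect detectable at this n", which is not what those tests probe. The signal
is routed through adipsin/CRP so that the ratio reported as most informative
in this literature is the recoverable truth.

What the generator deliberately does **not** emulate: real marginal
distributions of the markers, covariance between markers other than the
adiponectin pair, non-linear or interaction structure in the outcome, missing
data, and assay detection limits. Passing tests therefore demonstrate
correctness of the machinery on a known truth, not clinical performance.

`generate_validation_cohort()` produces the external-validation analogue: 80
subjects, 57 female / 23 male, BMI shifted +2 kg/m² to mimic a symptomatic
trial population of higher severity. It is used only for held-out
evaluation; `validate_external()` errors if any subject identifier overlaps
the training table.

## The 48-column design

`build_features()` expands a cohort into 12 dimensional variables plus the
36 ratios, $\binom{9}{2}$ unordered pairs. Ratio orientation is fixed by the
canonical marker order (adiponectin_HMW, adiponectin_LMW, adipsin, chemerin,
leptin, visfatin, CRP, IL8, MCP1): the stored column is earlier/later.
Because the literature quotes some ratios the other way around
("chemerin/adiponectin HMW"), `resolve_feature()` maps either orientation
onto the stored column, taking the reciprocal when needed; the
inverse-ratio study (`run_inverse_ratio_study()`, `invert_ratios()`)
evaluates the reciprocal design explicitly. `count_combinations()` uses the
multiplicative binomial formula with exact integer intermediates — every
value stays below $2^{53}$, so doubles carry them exactly and no factorial
is ever formed.

## PSOBVS

Particles carry 48 continuous scores; `decode_particle()` takes the top-$M$
scores (ties broken by canonical order) so every particle is an exact
size-$M$ subset, matching the one-model-per-size reporting convention.
Velocities follow the standard global-best update with inertia decaying
linearly 0.9→0.4, $c_1=c_2=2$, clamp ±4, swarm 30, 100 iterations — the
textbook values, since none are prescribed for this analysis. Two additions
counter premature convergence in the large lattice, where we observed the
swarm collapsing onto good decoys: after 15 stagnant iterations all but the
incumbent particle are re-scattered, and each search runs `n_starts = 3`
independent swarms (shared fitness cache) keeping the best. The reported
gbest trace is non-increasing by construction.

The wrapper fitness of a subset is
$0.7\,\mathrm{RMSE}_{\text{train}} + 0.3\,\mathrm{RMSE}_{\text{test}}$
averaged over $k = 4$ cross-validation folds — the weights proportional to
the 70/30 stage split. The surrogate regressor is, by default, least squares
solved from per-fold Gram matrices (a `ridge_lambda` conditioning penalty is
available but defaults to 0, with a pseudo-inverse guard for singular
systems); a small single-hidden-layer network (`surrogate = "ann"`, 8 hidden
units, weight decay $10^{-3}$) is available behind the same interface. The
linear surrogate is the default because the wrapper evaluates thousands of
subsets per search and the planted outcome is linear; fitness values are
memoised per subset within a search.

`monte_carlo_select()` repeats the search over independent resplits and
records per-feature selection frequencies; the final subset is the modal one
(ties by mean fitness). `select_subsets()` compares sizes by
$\mathrm{AIC} = n\ln(\mathrm{SSE}/n) + 2p$, $p = M + 1$. One numerical
design choice matters here: the SSE entering AIC is measured on a seeded 30%
scoring block that the search never sees, with the subset's coefficients fit
on the selection rows. The search examines so many subsets that the best
extra feature at any size has an inflated in-sample (and even out-of-fold)
association of roughly $2\ln(\#\text{candidates})$ — larger than the AIC
penalty of 2 — so any SSE measured on rows the search touched systematically
rewards one size too many; held-out rows restore the penalty's meaning.
`holdout = 0` switches to out-of-fold CV SSE for callers who want the
classical behaviour.

## ANFIS-FCM

`fcm_cluster()` is Bezdek's alternating optimisation with fuzziness
$m = 2$ (the universal convention). Rules are induced on the joint
input–output space (inputs z-scored with training statistics, target
standardised for clustering only), one rule per cluster; premises project
onto the inputs with Gaussian membership functions whose widths are
membership-weighted within-cluster standard deviations, floored at 5% of the
column sd so no width can collapse. Inference is standard first-order
Takagi–Sugeno: firing strength = product of Gaussian memberships, output =
normalised-firing-weighted average of linear rule consequents. Strengths are
max-shifted in log space, so the nearest rule fires even where all raw
products underflow.

Hybrid training alternates (1) a global linear least-squares solve of all
consequents with premises frozen — optimal given the premises, hence the
recorded RMSE after this pass never increases across epochs — and (2) one
guarded gradient step on premise centers and widths (initial rate 0.01 on
z-scored inputs, halved and reverted whenever a step would raise the
error). Defaults: 50 epochs, tolerance $10^{-10}$. Rank-deficient
least-squares systems fall back to the minimum-norm pseudo-solution. With
one rule the system is exactly ordinary linear regression, which the tests
exploit as an oracle. The number of rules, when not fixed, is chosen from
{2,…,5} by held-out error on an internal 70/30 split.

A trained system serialises to JSON (premise Gaussians, consequents, scaler,
input names) at 17 significant digits, so reloading reproduces predictions
bit-for-bit; `export_pseudocode()` additionally writes a rule-by-rule
IF/THEN listing sufficient for independent re-evaluation. This serialisation
is the portable "pseudocode" artifact of the pipeline.

## Evaluation statistics

`compute_metrics()` reports $R$ (Pearson), scatter index
$\mathrm{SI} = \mathrm{RMSE}/\overline{\mathrm{obs}}$ (mean-normalised; the
range-normalised variant exists in the literature but the mean form is
adopted and isolated here), $\mathrm{MAPE}$ (percent) and
$\mathrm{RMSRE} = \sqrt{\mathrm{mean}(((o-p)/o)^2)}$, plus the fraction of
samples with relative error under 10% and 15%. Relative errors always use
the observed value in the denominator; a zero observed value is a hard
error, never a silent skip. `uncertainty_band()` reports the standard
deviation of the forecasting error (SDFE) and the 95% band of halfwidth
$1.96 \times \mathrm{SDFE}$ about the bias-corrected prediction (reported as
both halfwidth and total width, to match either reading of "band width"),
with its empirical coverage. `taylor_stats()` emits the Taylor-diagram
coordinates and asserts the law-of-cosines identity
$\mathrm{cRMS}^2 = \sigma_o^2 + \sigma_p^2 - 2\sigma_o\sigma_p R$ to
$10^{-9}$ (population variances throughout). Plotting is left to the caller;
the module emits coordinates, not figures.

## The study pipeline

`stratify()` splits a cohort into Total, High-BMI (BMI ≥ 30 kg/m²,
inclusive cut) and Low-BMI, optionally by gender (coded 0 = female,
1 = male). `model5_features()` carries the published five-variable model per
group — age, gender, BMI, adipsin/CRP plus one group-specific variable
(Total: adipsin/chemerin; High-BMI: chemerin/adiponectin HMW; Low-BMI:
IL-8) — so the downstream studies can run without a fresh selection pass.

`run_ablation()` enumerates the sub-models of sizes 2–5 of a five-variable
model. Full enumeration gives $1+5+10+10 = 26$ models; the conventional
25-row labelling of this grid (M1–M25) can hold only 9 of the 10
three-variable models, and which one it omits is not recoverable, so the
package enumerates all 26 by default and `compat_view = TRUE` provides the
25-row compatibility labelling with the omitted subset flagged.

`run_gender_comparison()` fits one pooled and two gender-specific models on
identical row-level splits and reports per-gender MAPE improvements
$100(\mathrm{MAPE}_{\text{pooled}}-\mathrm{MAPE}_{\text{sep}})/\mathrm{MAPE}_{\text{pooled}}$.
Gender-specific models drop the gender column (constant within a stratum).
`run_inverse_ratio_study()` trains twins on the main and reciprocal designs
with identical splits. `validate_external()` is pure evaluation with a
runtime leakage guard on subject identifiers.

## Problem sizes and determinism

The test suite and the acceptance script exercise the pipeline at sizes a
single workstation handles comfortably: cohorts of 150–1000 subjects,
exhaustive oracles on 12-feature spaces (220 subsets at size 3), 20-seed
oracle and replicate studies, 10 Monte-Carlo resplits. These sizes were
chosen so that planted effects are recovered at many standard errors and
each study completes in seconds to a few minutes; they are the package's
own study conditions, stated here so results are interpretable.

All randomness — cohort draws, splits, FCM initialisation, swarm
trajectories — descends from explicit integer seeds through a deterministic
stream-splitting helper, and seeded internals restore the caller's RNG
state. Two runs under one master seed produce byte-identical JSON artifacts.

## Known limitations

* The synthetic generator is structurally faithful but not distributionally
  calibrated to any real cohort; absolute metric values on synthetic data do
  not transfer to clinical data.
* The exact published formulas for SI, RMSRE, SDFE and WUB, and the original
  ANFIS/PSO hyperparameters, are not available; standard definitions and
  textbook defaults are used, isolated behind the evaluation and
  configuration surfaces so they can be swapped without touching callers.
* Wrapper selection with a linear surrogate will not discover predictors
  whose effect is purely non-linear; the `"ann"` surrogate exists for that
  case but is far slower.
* AIC size choice uses a single held-out scoring block; with very small
  cohorts its variance is appreciable, and `holdout` can be raised or the
  Monte-Carlo repetition increased at cost.
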