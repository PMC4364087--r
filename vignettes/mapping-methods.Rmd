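---
title: "Mapping CFQ-R scores to EQ-5D-3L utilities: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping CFQ-R scores to EQ-5D-3L utilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfqrmap)
```

## The problem

Cost-effectiveness models need utilities — preference weights anchored at
1 (full health) and 0 (dead) — but cystic fibrosis trials typically collect
the CFQ-R, a 50-item disease-specific quality-of-life questionnaire, not the
EQ-5D. A mapping (crosswalk) function predicts the EQ-5D-3L utility from
CFQ-R scores so that existing CFQ-R datasets can feed QALY calculations.
`cfqrmap` implements the estimation, diagnostics and application machinery
for such mappings, and a synthetic cohort generator rich enough to exercise
every stage.

## Scoring models

**EQ-5D-3L.** A state is five ordinal levels (1–3) on mobility, self-care,
usual activity, pain/discomfort and anxiety/depression — 243 states in all.
The bundled UK TTO tariff scores a state as 1 minus a constant (any move
from full health), minus per-dimension level decrements, minus an N3 term if
any dimension is at level 3. The tariff file is validated at load against
its two printed anchors: state 11111 scores exactly 1 and state 33333 scores
−0.594 (the scale minimum, verified by brute force over all 243 states).
Other countries' tariffs can be supplied as plain-text files with the same
keys.

**CFQ-R.** Items (responses 1–4) are reverse-coded where flagged so higher
always means better health, then each of the 12 domains is the linear
rescale `100 · (mean − 1) / 3` of its item mean — the unique linear map
sending all-1s to 0 and all-4s to 100. The developer's official item→domain
map and reverse-coding list are licensed separately and not reproduced in
the public description of the instrument; the bundled map is therefore a
*declared assumption*, consistent with the published structure (50 items, 12
domains, item 43 the Respiratory mucus sub-question), and editable via a
config file. The half-scale missing-data rule (a domain needs ≥ 50% of its
items answered) is likewise a convention, not a printed fact, and is
configurable. Two facts that *are* printed drive the modelling views: the
Health-perceptions domain (redundant/collinear with the outcome construct)
and item 43 (a sub-question many respondents skip) are excluded from all
regression models, leaving 11 domains or 49 items.

## Estimators

Observed EQ-5D utilities are ceiling-inflated (about 19% at exactly 1) and
bounded, so three estimators are provided:

* **OLS** (`fit_ols`): closed form; reference estimator in the mapping
  literature despite the bounded outcome.
* **Tobit** (`fit_tobit`): Gaussian MLE with the outcome censored above at
  1, no lower censoring. Estimated by BFGS with analytic gradients on
  (β, log σ), started at OLS values. With zero censored observations the
  likelihood is the Gaussian likelihood, so the fit reproduces OLS — a
  tested equivalence. The `survival::survreg` implementation serves as an
  independent oracle in the test suite; it is never used in the fit path.
* **Two-part model** (`fit_tpm`): a logit for `P(utility = 1)` and a
  doubly-truncated Gaussian regression on (−0.594, 0.99) for the rest,
  combined as `EV = p + (1 − p) · ŷ₂`. The truncation interval is the range
  available to non-full-health utilities under the UK tariff (the largest
  attainable utility below 1 is 0.883, so 0.99 is a safe open bound).

**Part-2 prediction mode.** The default part-2 prediction is the *linear
predictor*, not the truncated-normal conditional mean. The source analysis
is silent on this point, but its reported TPM predictions reach 1 only
through part 1, which is consistent with linear-predictor predictions; this
also matches the default of the commercial software used there. The
conditional mean `E[y | a < y < b]` is available via
`predict(fit, type = "conditional")`.

**Numerics.** Both MLEs optimise over (β, log σ) with analytic gradients;
convergence requires optimizer success plus a per-observation gradient norm
below `sqrt(tol)` (default `tol = 1e-8`). Standard errors come from a
central-difference Hessian of the analytic gradient with per-parameter step
sizes — squared domain scores put design columns on the order of 10⁴
against coefficients of order 10⁻⁵, and a naively scaled finite-difference
Hessian is numerically singular there. Bias-corrected bootstrap intervals
(`bootstrap_bc`) implement the median-bias BC correction, not BCa: the
reference analysis says "bias-corrected" with no acceleration term. HC1
sandwich errors are the robust alternative; every report records which was
used and every resampling records its seed.

## The specification ladder

Models 1–8 are declarative (`model_spec`) and resolved against data by
`fit_spec`:

1. all 11 domains; 2. domains screened at p < 0.10; 3. model 2 plus
screened squared terms; 4. model 3 plus screened pairwise interactions;
5. all 49 items dummy-coded (reference = response 1, poor health); 6. items
screened at 10% by *joint Wald block tests* (dropping individual dummies
would break the ordinal coding); 7. model 6 with unordered items — dummy
coefficients not monotone from the reference — dichotomised to
best-level-vs-other; 8. a chosen base model plus age (years, linear) and
gender (single indicator).

Design choices where the source description was open, each a documented
assumption: screening is a single pass on the full fit, not stepwise;
squared-term candidates are squares of the retained domains only, themselves
screened at 10%; interactions are pairwise among retained domains; domain
scores enter uncentred on the 0–100 scale (the published coefficient
magnitudes, e.g. 0.00651 per point, confirm that scale); for the two-part
model *each part is screened on its own p-values*, which reproduces the
published structure in which the logit part retains three domains and the
truncated part seven. For the logit part of item-level models, sparse item
levels are merged toward worse health (`collapse_for_part1`) and capped at
3 levels, preventing quasi-separation. Model 8's base is an argument
(default: the item model 5, the base used in the reference analysis) rather
than hard-coded, since "best fitting" may differ per estimator family.

## Diagnostics and validation

RESET (powers 2–4 of fitted values, joint F) for OLS; linktest (refit on the
linear predictor and its square) for any family — on an OLS fit it
coincides with a power-2 RESET, an equality the tests assert. Verdicts use
a 0.05 threshold; the source reports verdicts without printing one, so this
is a documented convention. The ICC is the two-way random-effects,
absolute-agreement, single-measures variant (the source does not name one);
it penalises level shifts that leave the Pearson correlation untouched.
Utility bands for subgroup tables are left-closed/right-open with the last
band closed at 1 — an explicit convention, since the printed bands leave
boundary handling unstated. Cross-validation uses 4 random folds (sizes
differing by at most 1 when n is not divisible by 4), refits on 75%,
predicts the held-out 25%, and runs a one-way ANOVA on observed means across
folds as a balance check.

## The synthetic cohort generator

There is no deposited respondent-level dataset, so the generator *is* the
test bed. One standard-normal latent health trait per respondent drives:

* **EQ-5D dimensions** via ordinal thresholds on `ρ·trait + noise`. The
  five dimensions' relative threshold profile is fixed (fewest problems in
  self-care, most in pain and mood — a plausible adult-CF profile and a
  declared choice); a global shift, a level-2→3 gap scale and the loading ρ
  are calibrated so the implied utility distribution matches the three
  printed marginals: 19% at ceiling, 3% negative, mean 0.67. Calibration is
  *deterministic* — expected marginals are computed by quadrature over the
  trait and enumeration of the 243 states, so no Monte-Carlo tuning and no
  seed sensitivity; the calibrated loading comes out at ρ ≈ 0.50.
* **CFQ-R items** via per-domain loadings plus domain-shared and
  item-specific noise, with item thresholds solved in closed form so each
  domain's expected score equals the published total-sample domain mean
  (Physical 45.71, …, Digestive 71.27). Digestive symptoms gets a
  near-zero loading (0.05): it was the only domain not tracking lung
  function. The other loadings (0.45–0.85) encode a plausible severity
  gradient; the trait strength linking CFQ-R to EQ-5D is a free calibration
  parameter of this package, *not* an estimate from the study, which prints
  no such correlation.
* **Demographics**: age 28.7 ± 8.88 truncated to 18–62, 38.9% male, FEV1
  %-predicted 65.7 ± 27.3 clamped to 17–99 and correlated 0.6 with the
  trait, severity bands mild > 70 / moderate 41–70 / severe < 41.

What a green test on this cohort establishes: the estimators, ladder and
validation machinery behave correctly on data with the right marginals,
ceiling structure and cross-instrument dependence. What it does not: the
generator does not reproduce the empirical joint distribution of the 401
respondents, so screened predictor sets, ICC levels and RMSEs on synthetic
cohorts are properties of the synthetic world and are not expected to match
the published Tables 3–5.

`generate_linear` is a separate, simpler harness — known linear-quadratic
coefficients, uniform predictors, Gaussian noise, optional censoring or
truncation — used for parameter-recovery tests against the published
coefficient values.

## The published mapper

`map_ols_model3` / `map_tpm_model3` apply the bundled published Model 3
coefficients (stored at full printed precision in
`inst/extdata/table6_model3.tsv`, never inline). Known limits, stated
rather than patched:

* The published table prints a single TPM constant (−0.22122). Its
  magnitude matches the utility scale, so it is stored as the *part-2*
  intercept; the part-1 logit intercept is represented as unavailable, and
  `map_tpm_model3` refuses to run unless the user supplies one (e.g. by
  refitting the logit part locally). It is never silently set to zero.
* Printed rounding (e.g. −0.00004 on squared terms) limits reproduction
  precision to about 1e-4 per 100² score units.
* Predictions are unclamped by default — the reference analysis reported
  OLS predictions up to 1.183 — with an always-recorded flag and an
  optional clamp to [−0.594, 1] for economic-model use.
* The short published labels ("Emotion", "Eat", "Digest") are assumed to
  denote the Emotional-functioning, Eating-disturbances and
  Digestive-symptoms domains; the alias map (`domain_aliases()`) makes the
  assumption explicit and accepts both label styles.

## Known limitations

CLAD/median regression, EQ-5D-5L and VAS scoring, child/parent CFQ-R
versions, and FEV1 as a mapping predictor are out of scope by design. The
bundled CFQ-R item map is a structural stand-in, not the licensed manual's
map; users scoring real CFQ-R data should supply the official map file.
Item-level published coefficients were never printed, so item models can be
fitted and validated here but not applied from published values.
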