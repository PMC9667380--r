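---
title: "Methods: within-trial cost-effectiveness and cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial cost-effectiveness and cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The evaluation

`trialcea` implements the health-economic evaluation run alongside a
three-arm randomized trial of internet-delivered self-management for
bipolar disorder: a moderated discussion forum (arm 1, the active
control), the forum plus psychoeducation modules (arm 2), and the forum,
psychoeducation and CBT-based interactive tools (arm 3). The analysis
takes an Australian health-sector perspective over a 12-month horizon
with quarterly assessments (months 0, 3, 6, 9, 12). Costs cover
intervention delivery plus self-reported use of medical, psychological,
acute-care and support services priced at 2018-19 Australian unit costs;
no discounting is applied because the horizon is one year. Effects are
measured two ways: improvement on the Montgomery-Åsberg Depression
Rating Scale (MADRS, the trial's primary outcome; lower scores are
better, and differences are expressed as the intervention's improvement
over control so positive always favours the intervention), and
quality-adjusted life years (QALYs) from SF-6D utilities.

## Microcosting of delivery

Delivery is costed bottom-up. The website development and maintenance
total is split across arms by fixed complexity shares (0.19 / 0.38 /
0.43); computer leases and personnel time (forum monitoring and
debriefing, wages carrying a 25% employer overhead) are apportioned in
proportion to arm size, n_arm / N. Line items are held at full precision
and only rounded for reporting: half-up to cents for line items, half-up
to whole dollars for the per-participant averages. Column totals are
computed before rounding; the overall total is the sum of the rounded
arm totals, matching the conventions of published microcosting tables.
The per-capita delivery cost is attached to each participant's 3-month
record — the first post-randomization wave — and the participant's
health-sector total is delivery plus service costs summed over months
3–12. The baseline (month 0) cost is retained only as an adjustment
covariate. In the base case the total is defined only for participants
observed at all four follow-ups; model-based and imputation analyses
relax this.

## Outcomes

SF-6D scoring is table-driven: utility = 1 − Σ level decrements − a
"most severe" term when any dimension sits at its worst level, floored
at the instrument minimum (0.29). The published preference weights are
licensed, so the package ships only a clearly-labelled synthetic toy
table (`sf6d_toy_decrements_synthetic.csv`) for tests and examples;
real analyses supply the licensed table as a CSV. Whether the
most-severe adjustment applies is configurable and defaults to on.

QALYs use the trapezoid area under the piecewise-linear utility
trajectory: with quarterly waves each interval contributes
0.25 × (u_t + u_{t+1})/2 years, i.e. wave weights (0.125, 0.25, 0.25,
0.25, 0.125). A missing wave makes the QALY missing; how to proceed
(modelling, imputation) is an explicit caller decision, never silent
interpolation.

## Estimation

**Base case.** Follow-up outcomes are modelled jointly across the four
waves with an arm × wave cell-mean structure, adjusted for the baseline
value of the outcome, sex and national origin (the covariates specified
a priori), using generalized least squares with a fully unstructured
4 × 4 within-participant residual covariance estimated by REML
(`nlme::gls` with `corSymm` and `varIdent`). All available waves
contribute, so partially observed participants are retained; this is
the standard repeated-measures formulation in which the per-wave
adjusted differences are contrasts of model cells. The arm × wave
interaction is included because per-wave differences require it. The
3–12-month total-cost difference is the sum of the four per-wave cell
contrasts; the total QALY difference applies the trapezoid weights
(0.25, 0.25, 0.25, 0.125) to the follow-up utility contrasts (the
baseline weight cancels in adjusted differences); for MADRS the
12-month wave is the prespecified primary time point and serves as the
total-row effect. Confidence intervals use the normal approximation,
consistent with the bootstrap companion analyses; two-sided α = 0.05
throughout with no multiplicity adjustment. When REML cannot estimate
the covariance (for instance, numerically zero residual variance) the
same mean structure is refit by OLS and the result flagged.

**Sensitivity analyses.** The 3–12-month totals are analysed with
identity-link GLMs so that coefficients stay on the cost/QALY scale:
gamma family for costs, inverse-Gaussian for QALYs, gaussian for MADRS,
all with the same covariate set. Family choice is guided by the
modified Park test — regress log squared residuals on log predictions;
the slope estimates the power γ in Var(y) ∝ μ^γ and the family with
index nearest γ (gaussian 0, Poisson 1, gamma 2, inverse-Gaussian 3) is
recommended. Link adequacy combines the Pearson correlation of raw
residuals with predictions, the Pregibon test (refit on the linear
predictor and its square; test the squared term) and a modified
Hosmer–Lemeshow F test across deciles of the prediction. A numerical
note: for an ordinary least-squares fit the raw residuals are exactly
orthogonal to the fitted values, so the Pearson check is only
informative for genuinely non-gaussian fits; calibration of all three
tests is therefore demonstrated on identity-link gamma fits, where each
holds its ~5% level. Nonpositive outcomes under a positive-support
family are handled by a documented policy: shift by half the smallest
positive observed value, or fall back to a gaussian identity fit
(configurable; the shift is recorded on the result). Inverse-Gaussian
identity fits can fail to converge on noisy resamples; such fits fall
back to the gaussian identity GLM, which targets the same adjusted mean
difference.

## Bootstrap inference

Incremental pairs (ΔC, ΔE) are bootstrapped nonparametrically with 1000
iterations, resampling participants with replacement *within* arm so
the randomized arm sizes are preserved (the design is stratified; plain
pooled resampling would add between-arm size noise). An estimator
failure on a resample causes a redraw — never a dropped replicate — so
every distribution holds exactly B pairs, with the redraw count logged.

The ICER is ΔC/ΔE; a pair that is cheaper and more effective is
*dominant* (SE quadrant), costlier and less effective *dominated* (NW).
Effects smaller than 1e-9 in magnitude give no meaningful ratio and are
reported through net monetary benefit instead. Confidence intervals use
the reordered bootstrap percentile method: replicates are ordered by
angle on the cost-effectiveness plane, counterclockwise starting at the
positive-cost axis, so the ordering runs NW (dominated) → SW → SE
(dominant) → NE and economic preference is monotone along the arc that
bootstrap clouds occupy in practice. The α/2 and 1−α/2 order statistics
are the limits; a limit in the SE quadrant is reported as "dominant", in
the NW as "dominated", and when the cloud spans all four quadrants the
interval is flagged as hard to interpret. The original reordering
algorithm is cited but not restated in the source report, so this
ordering is a documented interpretation validated against a brute-force
angular-sort oracle in the test suite. The acceptability curve (CEAC)
reports, at each willingness-to-pay λ, the fraction of replicates with
λ·ΔE − ΔC > 0 (strict inequality; ties count as not cost-effective),
with the headline threshold at Aus $50,000 per QALY. Base-case reports
pair the repeated-measures point estimates with complete-case bootstrap
CIs, the hybrid used in the published sensitivity table.

## Missing data

A logistic regression of data completeness on sex, national origin, arm
and baseline outcome values screens for predictors of missingness
(degenerate outcomes and separation are flagged rather than reported).
The imputation sensitivity analysis nests a *single* chained-equation
imputation inside each bootstrap resample: wave-level costs, utilities
and MADRS scores are imputed in time order by predictive mean matching
(linear model on all other wave-level variables plus baseline values,
sex and national origin; a missing entry receives the observed value of
one of k = 5 donors with the nearest predictions, drawn uniformly; 10
cycles). Imputation is run separately within each randomized arm — the
standard recommendation for trials — so donors never cross arms; with
weak predictors and heavy missingness, pooled-donor matching would
otherwise shrink the between-arm difference, the very estimand of the
analysis. PMM only ever copies observed values, so imputed
entries stay in the observed support — important for the highly skewed
costs. With no missing data the procedure consumes no imputation
randomness and reduces exactly to the plain bootstrap under the same
seed. Defaults (k = 5, 10 cycles, wave order) are configurable.

## The synthetic trial generator

No trial data are deposited, so the package ships a generator that
reproduces the design's statistical structure: arms of 102/102/100; 82%
women; national origin 38.5% US / 33.5% Australia / 28% other; baseline
SF-6D utility mean 0.63 (SD 0.08, wave noise SD 0.05); a constant arm-2
utility drift planting a 12-month QALY gain of 0.012 (arm 3: 0.002);
arm-2 MADRS advantages of 4/5.5/3.6/3.8 points at the four follow-ups
(arm 3: 1.1/4.8/2.5/3.6); and mean 3–12-month service costs of
Aus $14,754 / 8,786 / 14,804 with total-cost SD targets
17,206 / 8,540 / 30,523 — SDs up to twice the means, as observed.
Absolute MADRS trajectories are calibrated only to the published
*differences* (baseline mean 20, SD 6, slight control improvement),
because arm-level means were not printed.

Service costs are generated as gamma-mixed Poisson counts: a gamma
latent intensity with the target category mean is divided by the unit
price and drawn through a Poisson. This keeps counts integer, makes
cost equal count × price exactly, preserves the target mean exactly (so
planted cost differences are exact estimands), and produces the heavy
right skew of real service-use costs. Within-arm category shares put
most control-arm cost in acute care, mirroring the reported pattern.
Gamma shapes are solved from the SD targets at scenario construction.

Wave completion follows a logistic MAR model on sex and wave (female
completion OR 0.6: sex was the only reported predictor of
incompleteness, its magnitude unprinted; 0.6 was fixed once) with
per-wave marginal completion solved to the observed
39.5/33.9/35.5/29.3%, plus a participant-level "engagement" intercept
(SD 4) making completion strongly correlated across waves. Baseline is
never removed, and deletion decisions never read outcome values, so the
mechanism is MAR by construction. Two honest limitations: with the
marginals fixed, no random-intercept model can push the fully-complete
fraction above the smallest marginal, so the generator yields ~19%
complete cases against the reported 27.6% (real completion was even
more nested); and each arm's costs are serially independent across
waves, whereas real service use is autocorrelated. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative model, not agreement with the unavailable trial data.
Each arm draws from its own seeded substream, so editing one arm's
parameters leaves the other arms' data untouched.

## Numerical choices and problem sizes

Currency is decimal 2018-19 AUD throughout; the US-dollar rate
(Aus $1 = US $0.7058) is metadata only. Rounding of reported money is
half-up (half-even would disagree with published tables). Wave
intervals are fixed at 0.25 years. The bootstrap uses B = 1000 for
reported analyses; validation simulations in the test suite use
200 trials × B = 500 for coverage, 500 datasets per family for the Park
test, 200 replicates for estimator recovery at the trial's n = 304, and
100 runs for imputation bias — sizes chosen to keep Monte-Carlo error
well below the tolerances they check while the whole suite runs on one
CPU in minutes. Seeds are explicit everywhere; a run is reproducible
from its manifest (seed, configuration hash, dataset fingerprint).

## Known limitations

Only the health-sector perspective is implemented (no patient time or
productivity costs); unit costs are Australian, so generalizability
follows the source evaluation's. The MADRS efficacy model of the parent
trial is consumed as per-wave adjusted differences when real estimates
are supplied, not re-derived. The reordered percentile ordering is an
interpretation (see above). The generator does not simulate SF-12 item
responses by default (utilities are drawn directly); an SF-12 profile
mode exists only to exercise the scoring table.
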