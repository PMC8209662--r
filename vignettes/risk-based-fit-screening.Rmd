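---
title: "Risk-based individualized FIT cut-offs: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-based individualized FIT cut-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitscreen)
library(ggplot2)
```

## The screening problem

Quantitative faecal immunochemical testing (FIT) screens for colorectal
cancer by measuring stool haemoglobin (µg Hb per gram of faeces) and
referring participants above a uniform concentration cut-off — commonly
20 µg Hb/g — to colonoscopy. A uniform cut-off ignores that the risk of
advanced neoplasia (AN: colorectal cancer or an advanced adenoma) at any
given FIT concentration rises with age and differs between the sexes. Two
screenees with identical FIT results can therefore carry quite different
probabilities of having AN found at colonoscopy, and an older screenee just
below the cut-off may be at higher absolute risk than a younger one just
above it.

fitscreen implements the alternative: model the risk of AN directly, refer
everyone whose *risk* exceeds a uniform risk threshold, and translate that
threshold back into the FIT concentration each age/sex profile needs to
reach it — an individualized cut-off table.

## The risk model

The core model is a logistic regression,

$$\operatorname{logit} P(\text{AN}) =
\beta_0 + \beta_1 F + \beta_2 \sqrt{F} + \beta_3\,\text{age} +
\beta_4\,\text{male},$$

with $F$ the FIT concentration. The $\sqrt{F}$ term captures the strongly
concave dose–response of AN risk in quantitative FIT: risk climbs steeply
over the first tens of µg Hb/g and flattens thereafter. With the reference
coefficients bundled as `cocos_risk_model()` ($\beta_1 < 0 < \beta_2$) the
risk curve rises up to $F = (\beta_2 / 2|\beta_1|)^2 \approx 261$ µg Hb/g —
far beyond any cut-off of interest — and declines afterwards, so all
screening-relevant behaviour sits on the rising branch.

Fitting (`fit_risk_model()`) is by penalized maximum likelihood: a ridge
penalty $\tfrac{\lambda}{2}\sum_j (\beta_j s_j)^2$ on the non-intercept
coefficients, with $s_j$ the sample SD of predictor $j$ so shrinkage acts
on the standardized scale. $\lambda$ is selected from a small grid
(default $\{0, 0.5, 1, 2, 4, 8, 16\}$) by corrected AIC with the effective
degrees of freedom $\operatorname{tr}[(X^TWX + P)^{-1} X^TWX]$.
Optimization is Newton–Raphson with step-halving, at most 100 iterations,
declaring convergence at a gradient max-norm below $10^{-8}$; the
covariance is the inverse penalized information matrix. At $\lambda = 0$
the fit coincides with the unpenalized MLE (the tests check agreement with
`stats::glm()` to $10^{-6}$).

Likelihood-ratio comparisons between nested predictor sets (`lr_test()`)
always refit both models unpenalized, because chi-square asymptotics for
the LR statistic do not hold under shrinkage.

Sex is coded male = 1, female = 0. This convention is pinned by the
reference worked example: inverting the bundled model at risk threshold
0.2524 must give 36.9 µg Hb/g for a 50-year-old woman and ≈9.5 µg Hb/g for
a 75-year-old man, which it does only under this coding.

## Threshold selection and cut-off inversion

Two ways of matching the risk-based rule to a uniform FIT cut-off are
provided:

* **Matched specificity** (`threshold_matched_specificity()`): candidate
  thresholds are the observed predicted risks (plus one above the maximum,
  so "refer nobody" is attainable); classification is risk ≥ threshold;
  the candidate minimizing the absolute specificity gap over disease-free
  participants wins, with ties broken toward the lower — more sensitive —
  threshold.
* **Matched positives** (`threshold_matched_positives()`): the k-th
  largest risk, with boundary ties expanded (everyone at the boundary risk
  is referred) and the realised count recorded.

Risk classification uses ≥, mirroring FIT positivity ("equal or higher
than" the cut-off).

Inversion (`invert_cutoff()`) solves, for each age/sex profile, the
quadratic in $x = \sqrt{F}$ obtained by equating the linear predictor to
the logit of the risk threshold. When $c$ (the remaining logit distance
after the age/sex offset) is positive the quadratic has two positive
roots; the smaller lies on the rising branch of the risk curve and is the
one reported — the larger root sits beyond the 261 µg/g vertex, where
reporting a *higher* concentration for a *lower* risk would be
nonsensical. Degenerate regimes are flagged rather than erroring:

* $c \le 0$: the profile reaches the threshold risk at FIT 0 —
  `always_positive`, cut-off 0 ("refer regardless of FIT");
* negative discriminant: the threshold exceeds the peak of the risk curve
  — `unreachable`;
* a positive cut-off below the assay limit of detection — `below_lod`,
  reported but flagged, because the detection floor of common FIT assays
  is around 2–5 µg Hb/g. The default `lod = 2` is configurable.

If a model without the expected coefficient signs is supplied, inversion
falls back to monotone 1-D root bracketing of the predicted risk. Every
`ok` or `below_lod` cut-off round-trips: the predicted risk at the
cut-off equals the threshold to $10^{-9}$. Display rounding of cut-off
tables is 0.1 µg Hb/g; raw values are retained.

```{r cutoffs, fig.width = 6, fig.height = 4}
tab <- cutoff_table(cocos_risk_model(), risk_threshold = 0.2524)
autoplot(tab)
range(tab$fit_cutoff_display)
```

## Evaluation

`confusion()`/`performance()` give sensitivity, specificity and
predictive values; undefined metrics (zero denominators) are flagged, not
errored. Confidence intervals are percentile bootstrap
(`bootstrap_ci()`), resampling participants with replacement, default
B = 2000 with an explicit seed. AUCs use the Mann–Whitney concordance
convention (ties credit 0.5 — relevant because many FIT values sit at the
detection floor) with DeLong variance, and paired AUC comparison uses the
DeLong test; both are delegated to the pROC package behind the package's
own surface, and the tests verify the AUC against an exhaustive
$O(n^2)$ pairwise oracle and the test's type-I error by null simulation.
`reclassification()` cross-tabulates FIT class against risk class by AN
stratum, reporting the number of participants the two rules disagree on.
`matched_sensitivity_table()` assembles the strategy comparison across a
ladder of reference cut-offs (default 10, 15, 20, 50 µg Hb/g).

## The synthetic cohort generator

No participant-level screening dataset ships with the package; instead
`generate_cohort()` draws cohorts that emulate the colonoscopy arm of the
COCOS trial, the setting in which this modelling approach was developed:
1112 participants, age truncated-normal(60.6, 6.2) on [50, 75] (sampled
by rejection), 51.2% male, and AN labels drawn from the logistic model
itself with the reference coefficients as truth — which makes parameter
recovery a well-posed test of the fitting code. Among AN cases, 7/101 are
CRC and the rest advanced adenomas; the lesion class feeds no statistic
and exists for realism of fixtures.

FIT concentration follows a two-part mixture: with probability
`fit_zero_mass` a uniform draw below the 2 µg Hb/g detection floor,
otherwise a lognormal. The published cohort reports only margins, not a
FIT distribution, so the mixture parameters are *calibrated*, not
asserted: `calibrate_fit_mixture()` tunes them so the analytic mixture
(Gauss–Legendre quadrature over FIT, age and sex — no simulation)
reproduces P(FIT ≥ 20) = 5.2% and AN prevalence = 9.1% to within 0.005.
The search is deterministic and exactly identified: the sub-LOD mass is
kept at its starting value, the lognormal location is solved in closed
form from the tail target, and the lognormal scale is root-bracketed on
the analytic prevalence, which is monotone decreasing in the scale once
the tail is pinned (a wider lognormal moves mass out of the moderate
concentrations where modelled risk is highest). The package defaults are
the calibrated values from a sub-LOD mass of 0.1, chosen among
{0.05, 0.1, 0.15} because its implied share of AN cases with FIT < 5 µg
Hb/g (62.4%) lies closest to the published 58.4%; that third moment is a
reported diagnostic, not a calibration target, and the generator is not
adjusted further.

```{r generator}
cfg <- cohort_config(seed = 20260922, n = 1112)
cohort <- generate_cohort(cfg)
cohort_summary(cohort)
config_moments(cfg)
```

What the generator does *not* emulate: the upper tail of the calibrated
lognormal is longer than any physical assay range (occasional draws in
the thousands of µg Hb/g); this is numerically harmless — predicted risk
beyond the vertex declines smoothly — and irrelevant to any cut-off
logic, but summaries of extreme quantiles should not be read as
realistic. It also omits colonoscopy quality, interval cancers,
screening-round history, and any FIT–age or FIT–sex dependence beyond
what the outcome model induces. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated generating
mechanism, not clinical performance on real screening data.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `run_pipeline()` derives a
per-stage sub-seed from the master seed by stage-indexed arithmetic so
adding a stage never perturbs earlier draws, and two runs with the same
configuration produce byte-identical artifacts. The test suite exercises
parameter recovery on 20 replicate cohorts of n = 20,000 (truth within
the 95% Wald interval in ≥ 90% of replicates per coefficient), type-I
error of the LR and DeLong tests on 1000-replicate null simulations
(n = 2000 and n = 200 respectively, acceptance band 3–7% at α = 0.05),
and Monte-Carlo agreement of a 100,000-participant cohort with the
analytic mixture moments — sizes chosen so the whole suite runs in a few
minutes on one core.

## Known limitations

* The published model's coefficients are bundled as rounded to 4 d.p.;
  worked-example reproductions inherit that rounding (the 75-year-old
  male cut-off computes to 9.43 µg Hb/g against the printed 9.5).
* The ridge penalty form and the CI method for sensitivity/specificity
  are conventions chosen here (standardized ridge with AICc selection;
  percentile bootstrap); other shrinkage or interval choices would give
  slightly different, equally defensible numbers.
* Bootstrap CIs are percentile intervals without acceleration or bias
  correction; for very rare outcomes at small n they can undercover.
* The generator draws covariates independently (age, sex, FIT), so any
  real-world correlation between age and FIT concentration is only
  induced through the outcome, not the covariates themselves.
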