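---
title: "Separating concavity effects from direct effects of income volatility on health"
author: "volhealth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating concavity effects from direct effects of income volatility on health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volhealth)
```

## The scientific problem

People whose incomes fluctuate from month to month tend to report worse
health than people with steady incomes at the same average level.  Part
of this association is mathematically inevitable: the relationship
between income and health is concave, so a bad month damages health more
than an equally sized good month improves it.  Averaged over time, a
volatile income stream therefore produces worse health than a steady
stream with the same mean — a Jensen-inequality ("concavity") effect
that exists even if volatility itself is harmless.  The substantive
question is whether the observed association is *stronger* than
concavity alone can produce, which would point to a direct cost of
volatility (for instance through uncertainty and stress) and would mean
that income-smoothing policies can improve population health without
raising anyone's average income.

`volhealth` implements the full analysis pipeline for monthly panel
data: one row per person-month with income, self-rated general health
(SRH, 1–9), and the GAD-7 and PHQ-8 symptom scales, whose average forms
the anxiety–depression composite (0–22.5; the two scales are highly
correlated and contribute about equally).

## The procedure

**Volatility statistics.**  A person's income volatility is the sample
standard deviation (divisor $n-1$) of their monthly incomes, in euros.
A person on a steady trajectory also has a large SD, so a time-adjusted
variant takes the SD of residuals from a per-person OLS regression of
income on month index.  The two are very highly correlated in data of
this kind; the simple statistic feeds the models by default and the
adjusted one is a sensitivity check.  The coefficient of variation is
computed for visualisation only: volatility is far from proportional to
mean income (the regression of one on the other has a material
intercept), so dividing by the mean does not remove the level
dependence.  Instead, all inferential models control for income level,
making the volatility coefficient a partial effect at a given income.

**Person-level models.**  For each outcome, averaged over a person's
observed months, we fit OLS of the mean outcome on
$\log(\bar y_i)$, $\log(\mathrm{SD}_i + \varepsilon_0)$, age and gender
(reference "woman").  Volatility can be exactly zero, so the log
transform needs an offset; $\varepsilon_0 = 1$ euro by default, and the
test suite checks that conclusions are insensitive to
$\varepsilon_0 \in \{0.1, 1, 10\}$.  Wald 95% confidence intervals and
two-sided t-tests accompany each estimate, and the variance explained by
each term is reported as partial $\eta^2 = SS_{term}/(SS_{term} +
SS_{res})$ with Type-III sums of squares (with no interactions these
coincide with Type II, so treatment contrasts are safe; exactly
collinear degenerate designs fall back to direct drop-one-term refits).

**Dose–response and concavity check.**  The month-level relationship
between income and each outcome is estimated with a penalized thin-plate
regression spline (basis dimension 10, smoothness by REML) — flexible
enough to capture the curvature precisely without a functional-form
assumption.  A parametric `log_linear` backend (outcome on
$\log(\text{income})$) is provided as the simpler alternative; it
captures concavity less sharply but leads to the same qualitative
conclusions.  Concavity is verified by evaluating first and second
derivatives of the fitted curve at every observed income (central finite
differences, step $10^{-3}\times$ the 99th-percentile income range) and
averaging: health outcomes scored positively should show a positive mean
first derivative and negative mean second derivative (downward concave),
symptom scores the reverse.  All incomes are used; nothing is truncated
except in plots.

**The decomposition.**  The fitted curve predicts, for each person-month,
the health expected from that month's income alone; averaging within
person gives *concavity-predicted* health — what each person should have
experienced given their income stream and the curvature, with no direct
volatility effect.  Refitting the identical person-level model with this
concavity-predicted outcome yields a volatility coefficient produced by
concavity alone.  The headline statistic is the ratio of the observed
volatility coefficient to this concavity-predicted one: ratios near 1
mean concavity explains the association; ratios well above 1 mean
volatility is associated with health beyond what curvature can produce.
The two models share transforms, covariates and complete-case sets so
the coefficients are directly comparable; if the two coefficients
disagree in sign the ratio is flagged unstable, and if the
concavity-predicted coefficient is numerically zero the ratio is
reported as undefined (the difference, `excess`, is always available).

**Multilevel triangulation.**  As an independent route, each monthly
report is a data point in a GAM with a month-level income smooth,
person-level age, gender and log-volatility fixed effects, and a
Gaussian random intercept per participant, all estimated jointly by fast
REML (the random intercept is a penalized ridge smooth — the standard
mixed-model-as-smooth formulation).  Because the smooth absorbs the
concave income effect at the month level, the volatility fixed effect
directly tests the association above and beyond concavity.

**Zero-volatility counterfactual.**  From the person-level model, each
person's predicted change in outcome if their volatility were zero
(volatility predictor set to $\log \varepsilon_0$, everything else held
fixed) is added to their observed outcome, simulating the outcome
distribution in a world without volatility.  The shift is summarised as
Hedges' $g$ (pooled-SD form with the small-sample correction
$1 - 3/(4(2n-2)-1)$; a paired-differences standardizer is available by
option), with a percentile bootstrap over persons for the interval, and
— for GAD-7 and PHQ-8 separately — as the percentage of persons whose
mean score lies strictly above 10, the conventional cutoff for clinical
concern.  The result object carries an explicit caveat: the exercise
assumes the adjusted association is entirely causal, so it is
illustrative rather than a quantitative causal prediction.

## The synthetic-data generator

Every stage is validated end-to-end on generated panels with known
ground truth (`generate_panel()`).  The generator emulates the structure
of the study population the package targets: 484 adults (25+) in the UK
and France reporting monthly for a year.

* **Reporting**: each person reports a month with probability drawn from
  a Beta distribution with mean 10/12 and concentration 1.5 — the
  heterogeneity reproduces a mean of ~10 reports with SD near 3, which a
  homogeneous binomial cannot.
* **Incomes**: person-mean incomes are lognormal (realised mean ≈ 3430,
  SD ≈ 1720 euros); monthly income is the person mean plus a linear
  trend (slope SD 150 euros/month, sized so the simple and
  time-adjusted volatility statistics correlate around 0.93) plus
  Gaussian shocks whose person-specific scale is lognormal and
  correlated with income level on the log scale (0.38, mapping to a
  raw-scale income–volatility correlation near 0.35).  A floor of 100
  euros keeps incomes positive; the lognormal mean parameter is set
  slightly low to absorb the floor's upward bias.
* **Outcomes**: latent health is a concave function of monthly income
  (default $a + c\log y$ with $c = 0.70$ for SRH and $-1.73$ for
  anxiety–depression, anchoring the realised outcome means at 6.10 and
  5.85), plus a centred direct volatility effect `beta_vol` per unit
  log shock scale, age and gender effects, a person random intercept,
  and month noise; SRH is rounded and clipped to 1–9.  GAD-7 and PHQ-8
  are generated around the latent anxiety–depression level with
  scale-specific person and month noise solved at generation time so
  their person means correlate at the 0.86 target (one corrective
  rescaling step compensates the attenuation that rounding and clipping
  to the bounded scale ranges introduce).  Clipping-induced bias is
  accepted as a realistic feature of bounded instruments.
* **Missingness**: each outcome is independently missing in ~1.2% of
  months, and ~6/484 persons lack age, reproducing a small model-level
  complete-case drop.
* **Defaults for the direct effect**: `beta_vol = (-0.12, 0.48)` — the
  excess association (observed minus concavity-predicted coefficient) of
  the regime the generator emulates, which anchors the observed
  volatility coefficients near −0.18 (SRH) and +0.5 to +0.6
  (anxiety–depression).

The generator deliberately does *not* emulate UK/France cultural
differences, cost-of-living covariates, serially correlated shocks,
occupation-linked third variables, or non-Gaussian shock distributions.
Passing tests therefore show that the pipeline recovers what it claims
under the stated data-generating process, not that real data are free of
confounding — the same limitation the counterfactual caveat records.

### Calibration to a target decomposition ratio

`calibrate_beta_vol()` tunes the direct effect so the *fitted* observed
coefficient is a chosen multiple of the *fitted* concavity-predicted
coefficient.  This cannot be done by simple rescaling, for two reasons
discovered during development and worth recording.  First, the generator
applies the effect on the latent shock scale $\log(s_i + \varepsilon_0)$
while the model regresses on the realised statistic
$\log(\mathrm{SD}_i + \varepsilon_0)$; sampling noise in an SD over ~10
observations, trend leakage and outcome clipping attenuate the fitted
coefficient to roughly 0.6 of the injected effect.  Second, because
volatility and income level are correlated, a direct volatility effect
leaks into the month-level dose–response fit and inflates the
concavity-predicted coefficient itself.  The calibration therefore
solves the fixed point $\hat\beta_{obs}(\beta) = R \cdot
\hat\beta_{conc}(\beta)$ by Newton iteration on simulated panels, with a
response slope estimated by common-random-number differencing against
the null.

### The ground-truth oracle

`implied_concavity_coefficient()` applies the generator's *true* curve
to each observed income, averages within person, and fits the standard
person-level model to those noiseless predictions.  It is the
coefficient a volatility regression must show under pure concavity, and
involves no fitted smoother, so it independently calibrates the
decomposition: under the null (`beta_vol = 0`) the observed
coefficient's CI should cover it at the nominal rate and the fitted
decomposition ratio should average 1.

## Numerical choices

* Thin-plate bases are built from at most 200 distinct income values
  (`max.knots`); at these data sizes the full eigen-decomposition over
  ~5000 distinct values costs two orders of magnitude more time for no
  visible change in the penalized fit.
* The multilevel engine uses `mgcv::bam(method = "fREML",
  discrete = TRUE)` — fast restricted likelihood with covariate
  discretisation — because a 484-level random-intercept smooth under
  plain `gam` is ~20× slower for the same estimates.
* Both volatility statistics use divisor $n-1$ so they are directly
  comparable (a pure-trend person then has adjusted volatility exactly 0
  while the simple statistic is positive); the residual-df $n-2$
  alternative is a flag.  Group computations centre incomes within
  person before forming sums of squares and snap volatilities below
  $10^{-10}$ of the income level to exact zero, so "all incomes equal"
  yields exactly zero.
* Derivative step: $10^{-3}\times$(99th-percentile income − minimum).
  Incomes outside a fit's training range are clamped before derivative
  evaluation, with the clamped count reported.
* Bootstrap CIs are percentile intervals over persons with the same
  resampled indices in both arms (the samples are paired).

## Validation design and problem sizes

The test suite validates each operation against an independent oracle
(closed forms for Jensen gaps and Hedges' g; two-pass and
normal-equations computations for the volatility statistics; noiseless
linear models recovered exactly; drop-one-term refits for partial
$\eta^2$), property-style invariants (scale equivariance,
permutation invariance, Schur-concavity of concavity-predicted means,
counterfactual monotonicity), and simulation batteries at the study's
own size: 200 null panels of 484 persons for decomposition calibration
and CI coverage, 200 panels with the direct effect calibrated to a
ratio of 3 for recovery, and random-intercept recovery at $\tau = 1$.
Smaller panels (60–300 persons) are used where a property does not need
the full size, keeping the default suite within a few minutes.

## Known limitations

* The decomposition ratio carries no uncertainty interval (an optional
  bootstrap would be experimental); at $n \approx 484$ its
  single-panel sampling SD is large (~0.8), which is why calibration
  checks average over many panels — and why `scripts/acceptance.R`
  reports Monte-Carlo means over 40 panels rather than one draw.
* The counterfactual inherits every assumption of the person-level
  model; it is a model projection, not a causal forecast.
* The multilevel engine fits Gaussian responses with a random intercept
  only — no random slopes, no residual autocorrelation.
* GBP→EUR conversion is a single configurable rate (default 1.15), not
  a time-varying exchange series.
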