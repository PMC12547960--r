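# volhealth

Analysis of month-to-month **income volatility and health** in
longitudinal panel data, with a decomposition that separates the
mechanical **concavity (Jensen) effect** of a curved income–health
relationship from a **direct effect of volatility itself**.

The package is aimed at epidemiologists and social scientists working
with intensive longitudinal panels in which people report, once a month,
the income they received plus health measures: self-rated general health
(SRH, 1–9) and the GAD-7 / PHQ-8 symptom scales (their average is the
anxiety–depression composite, 0–22.5).

## The core idea

Let $h(y)$ be the dose–response of health on monthly income $y$.  If
$h$ is concave, then for a person alternating between incomes $L$ and
$H$ with mean $M = (L+H)/2$,

$$h^{*} = \tfrac{1}{2}\{h(L) + h(H)\} \;<\; h(M),$$

so volatility must depress time-averaged health even if it has no
direct effect — a Jensen gap.  The pipeline quantifies how much of the
observed volatility–health association this mechanism explains:

1. **Volatility**: per person, the SD of monthly incomes (and a
   time-adjusted variant, the residual SD from a per-person regression
   of income on month).
2. **Observed association**: OLS of the person-mean outcome on
   $\log(\bar y_i)$, $\log(\mathrm{SD}_i + \varepsilon_0)$, age and
   gender, with partial $\eta^2$ per term.
3. **Concavity-predicted association**: a penalized thin-plate spline
   (GAM, REML smoothness) of the outcome on month-level income gives
   $\hat h$; averaging $\hat h(y_{it})$ within person gives the health
   each person should have had from their incomes and the curvature
   alone; the identical OLS refit on that outcome gives the coefficient
   concavity alone can produce.  Derivatives of $\hat h$ at every
   observed income verify the concavity direction.
4. **Decomposition ratio** = observed / concavity-predicted volatility
   coefficient.  ≈1: concavity explains everything.  ≫1: volatility is
   associated with health beyond concavity.
5. **Multilevel triangulation**: month-level GAM with an income smooth,
   a participant random intercept and person-level log volatility.
6. **Zero-volatility counterfactual**: predicted outcome shift if every
   person kept their mean income but had zero volatility, summarised as
   Hedges' $g$ and, for GAD-7/PHQ-8, the percentage of persons above
   the clinical cutoff of 10.

A synthetic-panel generator with known ground truth (income level and
shock-scale distributions, concave curves, direct effects, random
intercepts, correlated GAD/PHQ pair) makes the whole pipeline testable
end-to-end, including a ground-truth oracle for the coefficient implied
by pure concavity.

## Worked example

```r
library(volhealth)

sim   <- generate_panel(generator_config(), seed = 2026)  # 484 persons
agg   <- aggregate_person(sim$panel)
model <- fit_person_model(agg, "mean_srh")
model
#> Person-level model of mean_srh (income and volatility log-transformed)
#>               term estimate               ci       p partial_eta_sq
#>        (Intercept)    2.634   0.395 to 4.874 2.1e-02             NA
#>     average_income    0.610   0.349 to 0.872 5.9e-06          0.044
#>  income_volatility   -0.242 -0.410 to -0.074 4.8e-03          0.017
#>                age    0.002  -0.012 to 0.015 8.3e-01          0.000
#>         gender_man    0.059  -0.195 to 0.312 6.5e-01          0.000
#>       gender_other    0.049  -1.076 to 1.174 9.3e-01          0.000
#> Observations 468 (dropped 13 incomplete); R2 0.050 / adj 0.039
```

Higher volatility predicts worse self-rated health (−0.242 per unit log
volatility) after controlling for income level, explaining a share of
variance (partial η² 0.017) of the same order as income itself.  Is that
just concavity?

```r
fit <- fit_dose_response(sim$panel, "srh")          # penalized spline
concavity_check(fit, sim$panel$income[!is.na(sim$panel$srh)])
#> Concavity check over 4774 observed incomes (0 clamped to range):
#>   mean first derivative  0.000263 per euro
#>   mean second derivative -2.03e-07 per euro^2 (-0.203 per kEUR^2)
#>   orientation: downward_concave

cp <- concavity_predicted_outcomes(fit, sim$panel)
agg$.cp <- cp$concavity_predicted[match(agg$person_id, cp$person_id)]
aggc <- agg[agg$person_id %in% model$data$person_id, ]
decomposition(model, fit_person_model(aggc, ".cp"))
#> Volatility-association decomposition
#>   observed coefficient             -0.2421
#>   concavity-predicted coefficient  -0.1118
#>   ratio  2.17
#>   excess -0.1303 (association beyond concavity)
```

The curve rises and is downward concave, so some volatility association
is inevitable — but the observed coefficient is 2.17 times what
concavity predicts: most of the association is *not* explained by
curvature (this panel was generated with a direct volatility effect).
The counterfactual translates the association into population terms:

```r
set.seed(1)
zero_volatility_counterfactual(fit_person_model(agg, "mean_gad7"),
                               cutoff = 10, boot = 2000)
#> Zero-volatility counterfactual for mean_gad7 (n = 468)
#>   mean actual 5.631 -> mean counterfactual 2.635
#>   Hedges' g = 0.782 (95% CI 0.742 to 0.833)
#>   % above cutoff 10: actual 14.5, counterfactual 3.0
#>   NOTE: Illustrative only: assumes the adjusted volatility association
#>   is entirely causal.
```

`run_full_analysis()` chains every stage (including the multilevel
triangulation) and writes a traceable report bundle;
`inst/cli/volhealth.R` exposes the stages as shell commands
(`simulate`, `aggregate`, `fit`, `decompose`, `multilevel`,
`counterfactual`, `all`).

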