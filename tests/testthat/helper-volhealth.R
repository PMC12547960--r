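# Small hand-constructed panel: 3 persons x 4 months with assorted
# missingness, used for aggregation and IO oracles.
toy_panel <- function() {
  data.frame(
    person_id = rep(c("A", "B", "C"), each = 4),
    country = rep(c("UK", "FR", "UK"), each = 4),
    month_index = rep(0:3, 3),
    income = c(1000, 1000, 1000, 1000,
               800, 1200, 900, 1100,
               2000, NA, 2200, 2400),
    currency = "EUR",
    srh = c(5, NA, 7, 6, 4, 4, 5, 5, 8, 8, NA, 9),
    gad7 = c(2, 3, 4, 3, 10, 12, 11, 9, 0, 1, 0, 2),
    phq8 = c(4, 5, 6, 5, 12, 14, 13, 11, 1, 0, 0, 1),
    age = rep(c(30, 45, 60), each = 4),
    gender = rep(c("woman", "man", "other"), each = 4),
    stringsAsFactors = FALSE
  )
}

# Generator config under the pure-concavity null (no direct volatility
# effect), at a configurable size.
null_config <- function(n = 484, ...) {
  generator_config(n_persons = n, beta_vol = c(srh = 0, anxdep = 0), ...)
}

# Person-aggregate table built directly (bypassing a panel) with an
# exactly known linear data-generating process; used to check model fits
# against closed-form coefficients.
exact_aggregates <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(
    person_id = sprintf("X%03d", seq_len(n)),
    mean_income = exp(rnorm(n, 8, 0.5)),
    volatility = c(0, 0, 0, exp(rnorm(n - 3, 6, 1))),
    volatility_detrended = NA_real_,
    age = sample(25:70, n, replace = TRUE),
    gender = factor(sample(c("woman", "man", "other"), n, replace = TRUE,
                           prob = c(0.45, 0.45, 0.1)),
                    levels = c("woman", "man", "other")),
    stringsAsFactors = FALSE
  )
}

# One full decomposition replicate on a generated panel: observed model,
# spline dose-response, concavity-predicted model, plus the ground-truth
# oracle coefficient and the zero-volatility effect size.
decomposition_rep <- function(cfg, seed, outcome = "srh") {
  oc_col <- paste0("mean_", outcome)
  sim <- generate_panel(cfg, seed = seed)
  agg <- aggregate_person(sim$panel)
  obs <- fit_person_model(agg, oc_col)
  fit <- fit_dose_response(sim$panel, outcome)
  cp <- concavity_predicted_outcomes(fit, sim$panel)
  agg$.cp <- cp$concavity_predicted[match(agg$person_id, cp$person_id)]
  aggc <- agg[agg$person_id %in% obs$data$person_id, ]
  dec <- decomposition(obs, fit_person_model(aggc, ".cp"))
  oracle <- implied_concavity_coefficient(sim$truth, sim$panel, outcome,
                                          aggregates = agg)
  vc <- volatility_coef(obs)
  cf <- zero_volatility_counterfactual(obs, cutoff = NULL, boot = 0)
  c(ratio = dec$ratio, observed = dec$observed_coef,
    concavity = dec$concavity_coef, oracle = oracle,
    covered = as.numeric(vc$ci_low <= oracle & oracle <= vc$ci_high),
    g = cf$hedges_g$g)
}
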