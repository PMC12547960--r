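#' Run the full volatility-and-health analysis
#'
#' Orchestrates the whole pipeline on a monthly panel: person-level
#' aggregation and volatility statistics, person-level models of the
#' observed outcomes, the dose-response fit with concavity check,
#' concavity-predicted outcomes and the observed-versus-concavity
#' decomposition, the multilevel triangulation, and the zero-volatility
#' counterfactual (including GAD-7/PHQ-8 clinical-cutoff prevalences).
#'
#' @param panel A validated [monthly_panel], or `NULL` to generate one.
#' @param config A [generator_config()] used when `panel` is `NULL`.
#' @param seed Seed for panel generation and the bootstrap.
#' @param outcomes Outcomes to analyse (default `c("srh", "anxdep")`).
#' @param backend Dose-response backend, `"penalized_spline"` or
#'   `"log_linear"`.
#' @param eps0 Offset for `log(volatility + eps0)`, euros.
#' @param detrended Use time-adjusted instead of simple volatility in the
#'   models.
#' @param boot Bootstrap resamples for counterfactual CIs.
#' @param multilevel Fit the multilevel triangulation models (default
#'   `TRUE`; they are the slowest stage).
#' @param scale_counterfactuals Also refit per constituent scale (GAD-7,
#'   PHQ-8) for clinical-prevalence counterfactuals (default `TRUE`).
#' @param output_dir If non-`NULL`, write all stage outputs (CSV/JSON)
#'   there.
#' @return Object of class `"volhealth_report"`: a list with elements
#'   `aggregates`, `level_dependence`, `volatility_statistic_correlation`,
#'   `models`, `dose_response`, `concavity`, `decomposition`,
#'   `multilevel`, `counterfactual`, `scales`, `dropped`, `settings`.
#' @export
run_full_analysis <- function(panel = NULL, config = generator_config(),
                              seed = 1,
                              outcomes = c("srh", "anxdep"),
                              backend = c("penalized_spline", "log_linear"),
                              eps0 = 1, detrended = FALSE, boot = 1000,
                              multilevel = TRUE,
                              scale_counterfactuals = TRUE,
                              output_dir = NULL) {
  backend <- match.arg(backend)
  truth <- NULL
  if (is.null(panel)) {
    sim <- generate_panel(config, seed = seed)
    panel <- sim$panel
    truth <- sim$truth
  } else {
    panel <- validate_panel(panel)
  }
  set.seed(seed)

  agg <- aggregate_person(panel)
  dep <- volatility_level_dependence(agg)
  both <- stats::complete.cases(agg$volatility, agg$volatility_detrended)
  vol_cor <- if (sum(both) >= 3) {
    stats::cor(agg$volatility[both], agg$volatility_detrended[both])
  } else NA_real_

  outcome_col <- c(srh = "mean_srh", anxdep = "mean_anxdep",
                   gad7 = "mean_gad7", phq8 = "mean_phq8")
  models <- list(); fits <- list(); checks <- list()
  cp_models <- list(); decomps <- list(); mls <- list(); cfs <- list()
  dropped <- list()

  for (oc in outcomes) {
    obs <- fit_person_model(agg, outcome = outcome_col[[oc]], eps0 = eps0,
                            detrended = detrended)
    models[[oc]] <- obs
    dropped[[oc]] <- obs$n_dropped

    fit <- fit_dose_response(panel, outcome = oc, backend = backend)
    fits[[oc]] <- fit
    d_month <- month_level_data(panel, oc)
    checks[[oc]] <- concavity_check(fit, d_month$income)

    cp <- concavity_predicted_outcomes(fit, panel)
    agg_cp <- agg
    agg_cp$.cp <- cp$concavity_predicted[match(agg$person_id, cp$person_id)]
    # restrict to the observed model's persons so the two coefficient
    # tables are comparable
    agg_cp <- agg_cp[agg_cp$person_id %in% obs$data$person_id, ]
    cp_model <- fit_person_model(agg_cp, outcome = ".cp", eps0 = eps0,
                                 detrended = detrended)
    cp_models[[oc]] <- cp_model
    decomps[[oc]] <- decomposition(obs, cp_model)

    if (multilevel) {
      mls[[oc]] <- fit_multilevel(panel, outcome = oc,
                                  include_volatility = TRUE, eps0 = eps0,
                                  detrended = detrended)
    }
    cfs[[oc]] <- zero_volatility_counterfactual(obs, cutoff = NULL,
                                                boot = boot)
  }

  scales <- list()
  if (scale_counterfactuals) {
    for (sc in c("gad7", "phq8")) {
      m <- fit_person_model(agg, outcome = outcome_col[[sc]], eps0 = eps0,
                            detrended = detrended)
      scales[[sc]] <- zero_volatility_counterfactual(m, cutoff = 10,
                                                     boot = boot)
    }
  }

  report <- list(
    aggregates = agg,
    level_dependence = dep,
    volatility_statistic_correlation = vol_cor,
    models = models,
    dose_response = fits,
    concavity = checks,
    concavity_models = cp_models,
    decomposition = decomps,
    multilevel = mls,
    counterfactual = cfs,
    scales = scales,
    dropped = dropped,
    truth = truth,
    settings = list(backend = backend, eps0 = eps0, detrended = detrended,
                    boot = boot, seed = seed, outcomes = outcomes)
  )
  class(report) <- "volhealth_report"
  if (!is.null(output_dir)) write_report(report, output_dir, panel = panel)
  report
}

#' Write a full report bundle to disk
#'
#' Serializes every stage output of [run_full_analysis()]: the panel and
#' aggregates as CSV, coefficient tables for observed and
#' concavity-predicted models, decomposition ratios and counterfactual
#' summaries as JSON, and a run log of settings and dropped observations.
#'
#' @param report A `"volhealth_report"`.
#' @param output_dir Directory (created if needed).
#' @param panel Optionally, the panel to include in the bundle.
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir, panel = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(output_dir, ...)
  if (!is.null(panel)) write_panel(panel, fp("panel.csv"))
  write_aggregates(report$aggregates, fp("aggregates.csv"))
  for (oc in names(report$models)) {
    write_coefficient_table(report$models[[oc]],
                            fp(paste0("model_observed_", oc, ".csv")))
    write_coefficient_table(report$concavity_models[[oc]],
                            fp(paste0("model_concavity_", oc, ".csv")))
    write_counterfactual(report$counterfactual[[oc]],
                         fp(paste0("counterfactual_", oc, ".csv")))
  }
  summarise_cf <- function(cf) {
    list(hedges_g = cf$hedges_g$g, g_ci_low = cf$hedges_g$ci_low,
         g_ci_high = cf$hedges_g$ci_high,
         prevalence_actual = cf$prevalence_actual,
         prevalence_cf = cf$prevalence_cf, caveat = cf$caveat)
  }
  summary <- list(
    level_dependence = report$level_dependence,
    volatility_statistic_correlation =
      report$volatility_statistic_correlation,
    decomposition = lapply(report$decomposition, unclass),
    concavity = lapply(report$concavity, unclass),
    multilevel = lapply(report$multilevel, function(m) {
      list(fixed = m$fixed, ranint_sd = m$ranint_sd, n_obs = m$n_obs,
           n_persons = m$n_persons)
    }),
    counterfactual = lapply(report$counterfactual, summarise_cf),
    scales = lapply(report$scales, summarise_cf),
    dropped = report$dropped,
    settings = report$settings
  )
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.volhealth_report <- function(x, ...) {
  cat("== Income volatility and health: analysis report ==\n\n")
  cat(sprintf("Persons: %d; income-volatility correlation with mean income: %.3f\n",
              nrow(x$aggregates), x$level_dependence$correlation))
  cat(sprintf("Simple vs time-adjusted volatility correlation: %.3f\n\n",
              x$volatility_statistic_correlation))
  for (oc in names(x$models)) {
    cat("--", toupper(oc), "--\n")
    print(x$models[[oc]])
    print(x$concavity[[oc]])
    print(x$decomposition[[oc]])
    if (length(x$multilevel)) print(x$multilevel[[oc]])
    print(x$counterfactual[[oc]])
    cat("\n")
  }
  for (sc in names(x$scales)) {
    cat("--", toupper(sc), "(clinical prevalence) --\n")
    print(x$scales[[sc]])
    cat("\n")
  }
  invisible(x)
}
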