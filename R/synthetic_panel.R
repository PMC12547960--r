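#' Configuration for the synthetic monthly-panel generator
#'
#' Builds the parameter list consumed by [generate_panel()].  Defaults are
#' anchored to the descriptive statistics of the study population the
#' package targets: 484 adults in the UK and France reporting monthly for
#' a year (about 10 reports each, SD about 3), right-skewed incomes
#' (person-mean about 3430 euros, SD about 1720), income volatility that
#' rises with income level (cross-person correlation about 0.35 between
#' mean income and volatility), a concave income-to-health dose-response,
#' person random intercepts, and GAD-7/PHQ-8 scores whose person means
#' correlate about 0.86.
#'
#' @param n_persons Number of persons (default 484).
#' @param n_months Number of study months (default 12, indices 0..11).
#' @param report_prob Mean per-month reporting probability (default 10/12,
#'   giving about 10 reports per person).
#' @param report_concentration Beta concentration `a + b` of the
#'   per-person reporting probability (default 1.5; the strong
#'   heterogeneity reproduces a report-count SD near 3 rather than the
#'   1.3 a homogeneous binomial would give).
#' @param income_meanlog,income_sdlog Lognormal parameters of the
#'   person-mean income; defaults give a realised monthly-income mean of
#'   about 3430 and person-mean SD of about 1720 euros (the meanlog sits
#'   slightly below `log(3430) - sdlog^2/2` to absorb the upward bias the
#'   income floor introduces).
#' @param vol_meanlog,vol_sdlog Lognormal parameters of the person
#'   month-to-month income shock SD; together with the trend component
#'   the realised volatility statistic has mean near 770 and SD above
#'   1000 euros, right-skewed.
#' @param vol_income_cor Correlation of log shock SD with log mean income
#'   (default 0.38, which maps to a raw-scale correlation between mean
#'   income and realised volatility near 0.35 for these lognormal
#'   margins once trend and floor effects are in play).
#' @param trend_sd SD of the per-person linear income slope, euros per
#'   month (default 150; steady trajectories on top of shocks, sized so
#'   the simple and time-adjusted volatility statistics correlate around
#'   0.93-0.94 across persons).
#' @param income_floor Lowest possible monthly income, euros (default
#'   100): Gaussian shocks are truncated here so incomes stay positive.
#' @param curve_srh,curve_anxdep Concave dose-response of each outcome on
#'   monthly income.  Either `c(intercept, slope)` for the log-linear form
#'   `intercept + slope * log(y)` (defaults anchor the population means at
#'   6.10 for self-rated health and 5.85 for anxiety-depression) or an
#'   arbitrary function of income.
#' @param beta_vol Named vector `c(srh=, anxdep=)`: direct effect of
#'   volatility on each outcome per unit `log(sd + eps0)`, over and above
#'   the concavity effect.  `c(0, 0)` is the pure-concavity null.  The
#'   defaults (-0.12, 0.48) equal the excess association (observed minus
#'   concavity-predicted volatility coefficient) of the study regime the
#'   generator emulates, and put the fitted decomposition ratio around
#'   2.5; [calibrate_beta_vol()] tunes the effect to an exact target
#'   ratio instead.  The effect is centred at `vol_meanlog` so changing
#'   it does not move outcome means.
#' @param tau Named vector of person random-intercept SDs.
#' @param sigma_eps Named vector of month-level residual SDs of the
#'   latent outcomes.
#' @param gad_phq_corr Target correlation of person-mean GAD-7 with
#'   person-mean PHQ-8 (default 0.86).  The scale-specific person-level
#'   variance is solved from this target at generation time.
#' @param scale_month_sd Month-level measurement SD unique to each of the
#'   GAD-7/PHQ-8 scales around the shared latent anxiety-depression level.
#' @param gad_mean,phq_mean Marginal scale means (defaults 5.50 / 6.01);
#'   their half-difference offsets the two scales around the latent level.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution
#'   (defaults 41.9, 10.5, 25..76 years).
#' @param gender_probs Probabilities of woman/man/other (defaults
#'   244/484, 234/484, 6/484).
#' @param age_effect,man_effect,other_effect Named vectors of covariate
#'   effects on each outcome (age centred at `age_mean`; gender effects
#'   centred so outcome means stay anchored).
#' @param covariate_missing Probability a person's age is missing
#'   (default 6/484, reproducing a handful of model-level complete-case
#'   drops).
#' @param outcome_missing Per-month probability that each health outcome
#'   is individually missing (default 0.012).
#' @param eps0 Offset used inside `log(volatility + eps0)` (default 1
#'   euro), shared with the model-fitting modules.
#' @param seed Integer seed; `generate_panel()` uses it unless overridden.
#' @return A list classed `"generator_config"`.
#' @export
generator_config <- function(n_persons = 484,
                             n_months = 12,
                             report_prob = 10 / 12,
                             report_concentration = 1.5,
                             income_meanlog = 8.018,
                             income_sdlog = 0.473,
                             vol_meanlog = 5.80,
                             vol_sdlog = 1.110,
                             vol_income_cor = 0.38,
                             trend_sd = 150,
                             income_floor = 100,
                             curve_srh = c(intercept = 0.59, slope = 0.70),
                             curve_anxdep = c(intercept = 19.09, slope = -1.73),
                             beta_vol = c(srh = -0.12, anxdep = 0.48),
                             tau = c(srh = 1.55, anxdep = 4.20),
                             sigma_eps = c(srh = 1.30, anxdep = 2.80),
                             gad_phq_corr = 0.86,
                             scale_month_sd = 2.40,
                             gad_mean = 5.50,
                             phq_mean = 6.01,
                             age_mean = 41.9,
                             age_sd = 10.5,
                             age_range = c(25, 76),
                             gender_probs = c(woman = 244, man = 234,
                                              other = 6) / 484,
                             age_effect = c(srh = 0, anxdep = -0.11),
                             man_effect = c(srh = 0.27, anxdep = -0.90),
                             other_effect = c(srh = 0, anxdep = 0),
                             covariate_missing = 6 / 484,
                             outcome_missing = 0.012,
                             eps0 = 1,
                             seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_persons >= 1, n_months >= 2,
            report_prob > 0, report_prob <= 1,
            report_concentration > 0,
            income_sdlog >= 0, vol_sdlog >= 0,
            abs(vol_income_cor) <= 1,
            trend_sd >= 0, income_floor > 0,
            all(tau >= 0), all(sigma_eps >= 0),
            gad_phq_corr >= -1, gad_phq_corr <= 1,
            scale_month_sd >= 0, eps0 > 0)
  for (nm in c("beta_vol", "tau", "sigma_eps", "age_effect", "man_effect",
               "other_effect")) {
    v <- cfg[[nm]]
    if (is.null(names(v)) || !all(c("srh", "anxdep") %in% names(v))) {
      stop("'", nm, "' must be a named vector with elements srh and anxdep",
           call. = FALSE)
    }
  }
  cfg$curve <- list(srh = as_curve_fun(curve_srh),
                    anxdep = as_curve_fun(curve_anxdep))
  class(cfg) <- "generator_config"
  cfg
}

# Coerce a curve spec (c(intercept, slope) log-linear form, or a function)
# to a function of income.
as_curve_fun <- function(spec) {
  if (is.function(spec)) return(spec)
  if (is.numeric(spec) && length(spec) == 2) {
    a <- unname(spec[1]); b <- unname(spec[2])
    return(function(y) a + b * log(y))
  }
  stop("curve must be a function or c(intercept, slope)", call. = FALSE)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic monthly panel with known ground truth
#'
#' Simulates a monthly income-and-health panel with the structure the
#' analysis modules assume.  Person `i` draws a mean income
#' `m_i` (lognormal), a linear monthly trend slope `b_i`, and a
#' shock scale `s_i` whose logarithm is correlated with `log(m_i)`;
#' month `t` income is `max(m_i + b_i (t - tbar) + e_it, floor)` with
#' `e_it ~ N(0, s_i)`.  Latent health outcomes are
#' `h(y_it) + beta_vol (log(s_i + eps0) - vol_meanlog) + covariate effects
#' + u_i + eps_it` with `h` the concave dose-response and `u_i` a person
#' random intercept; self-rated health is rounded and clipped to 1..9.
#' GAD-7 and PHQ-8 are generated as a correlated pair around the latent
#' anxiety-depression level (the per-scale person variance is solved so
#' their person means correlate at the configured target), then rounded
#' and clipped to their scale ranges.  Months are reported with a
#' person-specific Beta-distributed probability.
#'
#' @param config A [generator_config()] list.
#' @param seed Integer seed overriding `config$seed`.  Identical config
#'   and seed give byte-identical panels.
#' @return A list with elements `panel` (a validated [monthly_panel]) and
#'   `truth` (per-person `m`, `s`, `slope`, random intercepts, plus the
#'   curve functions, `beta_vol`, `eps0` and the seed used).
#' @export
generate_panel <- function(config = generator_config(), seed = NULL) {
  cfg <- config
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_persons
  Tm <- cfg$n_months

  ids <- sprintf("P%04d", seq_len(n))
  log_m <- stats::rnorm(n, cfg$income_meanlog, cfg$income_sdlog)
  m <- exp(log_m)
  gamma <- if (cfg$income_sdlog > 0) {
    cfg$vol_income_cor * cfg$vol_sdlog / cfg$income_sdlog
  } else 0
  omega <- cfg$vol_sdlog * sqrt(max(0, 1 - cfg$vol_income_cor^2))
  log_s <- cfg$vol_meanlog + gamma * (log_m - cfg$income_meanlog) +
    stats::rnorm(n, 0, omega)
  s <- exp(log_s)   # vol_meanlog = -Inf gives the zero-shock limit
  slope <- stats::rnorm(n, 0, cfg$trend_sd)
  u_srh <- stats::rnorm(n, 0, cfg$tau[["srh"]])
  u_anx <- stats::rnorm(n, 0, cfg$tau[["anxdep"]])
  age <- round(rtruncnorm1(n, cfg$age_mean, cfg$age_sd,
                           cfg$age_range[1], cfg$age_range[2]))
  gender <- sample(names(cfg$gender_probs), n, replace = TRUE,
                   prob = cfg$gender_probs)
  country <- sample(c("UK", "FR"), n, replace = TRUE,
                    prob = c(244, 240) / 484)
  p_rep <- stats::rbeta(n, cfg$report_concentration * cfg$report_prob,
                        cfg$report_concentration * (1 - cfg$report_prob))

  # centred direct-volatility and covariate effects keep outcome means at
  # the curve-implied level whatever beta_vol is set to; with a
  # degenerate (zero) shock scale the centre falls back to the realised
  # mean so the term is finite
  centre <- if (is.finite(cfg$vol_meanlog)) cfg$vol_meanlog else
    mean(log(s + cfg$eps0))
  vol_term <- log(s + cfg$eps0) - centre
  gender_centre <- function(man_eff, other_eff) {
    cfg$gender_probs[["man"]] * man_eff +
      cfg$gender_probs[["other"]] * other_eff
  }
  eff_srh <- cfg$beta_vol[["srh"]] * vol_term +
    cfg$age_effect[["srh"]] * (age - cfg$age_mean) +
    ifelse(gender == "man", cfg$man_effect[["srh"]],
           ifelse(gender == "other", cfg$other_effect[["srh"]], 0)) -
    gender_centre(cfg$man_effect[["srh"]], cfg$other_effect[["srh"]]) +
    u_srh
  eff_anx <- cfg$beta_vol[["anxdep"]] * vol_term +
    cfg$age_effect[["anxdep"]] * (age - cfg$age_mean) +
    ifelse(gender == "man", cfg$man_effect[["anxdep"]],
           ifelse(gender == "other", cfg$other_effect[["anxdep"]], 0)) -
    gender_centre(cfg$man_effect[["anxdep"]], cfg$other_effect[["anxdep"]]) +
    u_anx

  tbar <- (Tm - 1) / 2
  months <- 0:(Tm - 1)
  idx_p <- rep(seq_len(n), each = Tm)
  idx_t <- rep(months, times = n)
  income <- pmax(m[idx_p] + slope[idx_p] * (idx_t - tbar) +
                   stats::rnorm(n * Tm, 0, s[idx_p]),
                 cfg$income_floor)

  lat_srh <- cfg$curve$srh(income) + eff_srh[idx_p] +
    stats::rnorm(n * Tm, 0, cfg$sigma_eps[["srh"]])
  srh <- pmin(pmax(round(lat_srh), 1), 9)

  lat_anx <- cfg$curve$anxdep(income) + eff_anx[idx_p] +
    stats::rnorm(n * Tm, 0, cfg$sigma_eps[["anxdep"]])

  reported <- stats::runif(n * Tm) < p_rep[idx_p]

  # per-scale person variance solved from the target person-mean
  # correlation, using the realised between-person variance of the latent
  # anxiety-depression means over reported months
  lat_means <- tapply(lat_anx[reported], idx_p[reported], mean)
  v_shared <- stats::var(lat_means, na.rm = TRUE)
  n_rep_mean <- max(1, mean(tabulate(idx_p[reported], n)[
    tabulate(idx_p[reported], n) > 0]))
  r <- cfg$gad_phq_corr
  kappa2 <- if (r > 0 && is.finite(v_shared)) {
    max(0, v_shared * (1 - r) / r -
          cfg$scale_month_sd^2 / n_rep_mean - 1 / (12 * n_rep_mean))
  } else 0
  g_i <- stats::rnorm(n, 0, 1)
  p_i <- stats::rnorm(n, 0, 1)
  e_g <- stats::rnorm(n * Tm, 0, 1)
  e_p <- stats::rnorm(n * Tm, 0, 1)
  offset <- (cfg$phq_mean - cfg$gad_mean) / 2
  make_scales <- function(kap) {
    kap <- sqrt(max(kap^2, 0))
    gad <- pmin(pmax(round(lat_anx - offset + kap * g_i[idx_p] +
                             cfg$scale_month_sd * e_g), 0), 21)
    phq <- pmin(pmax(round(lat_anx + offset + kap * p_i[idx_p] +
                             cfg$scale_month_sd * e_p), 0), 24)
    list(gad = gad, phq = phq)
  }
  sc <- make_scales(sqrt(kappa2))
  # rounding and clipping to the bounded scale ranges attenuate the
  # achieved person-mean correlation slightly; one corrective step
  # rescales the scale-unique noise to restore the target
  if (r > 0 && r < 1) {
    pm_cor <- function(scpair) {
      gm <- tapply(scpair$gad[reported], idx_p[reported], mean)
      pmn <- tapply(scpair$phq[reported], idx_p[reported], mean)
      stats::cor(gm, pmn, use = "complete.obs")
    }
    ra <- pm_cor(sc)
    if (is.finite(ra) && ra > 0 && ra < 1) {
      shrink <- (1 / r - 1) / (1 / ra - 1)
      u_month <- cfg$scale_month_sd^2 / n_rep_mean + 1 / (12 * n_rep_mean)
      u_new <- (kappa2 + u_month) * shrink - u_month
      sc <- make_scales(sqrt(max(u_new, 0)))
    }
  }
  gad <- sc$gad
  phq <- sc$phq

  miss <- function(x) {
    x[stats::runif(length(x)) < cfg$outcome_missing] <- NA
    x
  }
  age_obs <- age
  age_obs[stats::runif(n) < cfg$covariate_missing] <- NA

  panel <- data.frame(
    person_id = ids[idx_p],
    country = country[idx_p],
    month_index = idx_t,
    income = income,
    currency = "EUR",
    srh = miss(srh),
    gad7 = miss(gad),
    phq8 = miss(phq),
    age = age_obs[idx_p],
    gender = gender[idx_p],
    stringsAsFactors = FALSE
  )[reported, ]
  rownames(panel) <- NULL
  panel <- validate_panel(panel)

  truth <- list(
    persons = data.frame(person_id = ids, mean_income_true = m,
                         vol_scale = s, slope = slope,
                         intercept_srh = u_srh, intercept_anxdep = u_anx,
                         report_prob = p_rep, stringsAsFactors = FALSE),
    curve = cfg$curve,
    beta_vol = cfg$beta_vol,
    eps0 = cfg$eps0,
    vol_meanlog = cfg$vol_meanlog,
    seed = seed,
    config = cfg
  )
  list(panel = panel, truth = truth)
}

#' Concavity-implied volatility coefficient (ground-truth oracle)
#'
#' Applies the generator's TRUE dose-response curve to each observed
#' monthly income, averages per person, and fits the standard person-level
#' model to those noiseless concavity predictions.  The volatility
#' coefficient of that fit is the association a volatility regression
#' should show under pure concavity; it calibrates the decomposition
#' without involving any fitted smoother.
#'
#' @param truth The `truth` element returned by [generate_panel()].
#' @param panel The matching `panel` element.
#' @param outcome `"srh"` or `"anxdep"`.
#' @param eps0 Offset for `log(volatility + eps0)` (defaults to the
#'   generator's).
#' @param aggregates Optional precomputed [aggregate_person()] result for
#'   the same panel (saves recomputation in simulation loops).
#' @return The implied volatility coefficient (a single number).
#' @export
implied_concavity_coefficient <- function(truth, panel,
                                          outcome = c("srh", "anxdep"),
                                          eps0 = truth$eps0,
                                          aggregates = NULL) {
  outcome <- match.arg(outcome)
  if (!all(unique(panel$person_id) %in% truth$persons$person_id)) {
    stop("panel and truth do not come from the same generation",
         call. = FALSE)
  }
  h <- truth$curve[[outcome]]
  cp <- tapply(h(panel$income), panel$person_id, mean, na.rm = TRUE)
  agg <- if (is.null(aggregates)) aggregate_person(panel) else aggregates
  agg$.cp <- as.numeric(cp[agg$person_id])
  fit <- fit_person_model(agg, outcome = ".cp", eps0 = eps0)
  fit$table$estimate[fit$table$term == "income_volatility"]
}

#' Calibrate the direct volatility effect to a target decomposition ratio
#'
#' Sets `beta_vol` for one outcome so that the *fitted* observed
#' volatility coefficient is `target_ratio` times the fitted
#' concavity-predicted coefficient, i.e. so the decomposition ratio of a
#' typical panel is `target_ratio`.
#'
#' Two attenuation effects make this a fixed-point problem rather than a
#' simple rescaling.  First, the generator applies the direct effect on
#' the latent shock scale `log(s_i + eps0)` while the fitted model
#' regresses on the realised statistic `log(sd_i + eps0)`, so sampling
#' noise in the realised SD, trend leakage and outcome rounding/clipping
#' attenuate how much of `beta_vol` reaches the fitted coefficient.
#' Second, because income level and volatility are correlated, a direct
#' volatility effect leaks into the month-level dose-response fit and
#' inflates the concavity-predicted coefficient itself.  The calibration
#' therefore iterates on the fitted-coefficient scale: it estimates the
#' response slope `lambda = d obs / d beta_vol` by common-random-number
#' differencing against the null, then Newton-updates `beta_vol` until
#' the simulated mean observed coefficient equals `target_ratio` times
#' the simulated mean concavity-predicted coefficient.
#'
#' @param config A [generator_config()].
#' @param target_ratio Desired observed / concavity-predicted ratio.
#' @param outcome Outcome to calibrate.
#' @param reps Panels per evaluation of the mean coefficients
#'   (default 16).
#' @param max_iter Newton iterations (default 3; convergence is
#'   typically reached in 2).
#' @param tol Stop when the residual on the observed-coefficient scale
#'   is below `tol` (default 0.005).
#' @param backend Dose-response backend for the concavity coefficient.
#' @param seed Seed for the calibration panels.
#' @return `config` with `beta_vol[outcome]` replaced (the other
#'   outcome's direct effect is set to 0).
#' @export
calibrate_beta_vol <- function(config, target_ratio,
                               outcome = c("srh", "anxdep"),
                               reps = 16, max_iter = 3, tol = 0.005,
                               backend = "penalized_spline",
                               seed = 1) {
  outcome <- match.arg(outcome)
  oc_col <- c(srh = "mean_srh", anxdep = "mean_anxdep")[[outcome]]
  fit_pair <- function(cfg, s, need_conc) {
    sim <- generate_panel(cfg, seed = s)
    agg <- aggregate_person(sim$panel)
    obs <- fit_person_model(agg, oc_col, eps0 = config$eps0)
    conc <- NA_real_
    if (need_conc) {
      fit <- fit_dose_response(sim$panel, outcome, backend = backend)
      cp <- concavity_predicted_outcomes(fit, sim$panel)
      agg$.cp <- cp$concavity_predicted[match(agg$person_id, cp$person_id)]
      aggc <- agg[agg$person_id %in% obs$data$person_id, ]
      conc <- volatility_coef(
        fit_person_model(aggc, ".cp", eps0 = config$eps0))$estimate
    }
    c(obs = volatility_coef(obs)$estimate, conc = conc)
  }
  seeds <- seed + seq_len(reps) - 1L
  eval_at <- function(beta, need_conc = TRUE) {
    cfg <- config
    cfg$beta_vol[] <- 0
    cfg$beta_vol[[outcome]] <- beta
    res <- vapply(seeds, function(s) fit_pair(cfg, s, need_conc),
                  c(obs = 0, conc = 0))
    c(obs = mean(res["obs", ]), conc = mean(res["conc", ]))
  }
  null_fit <- eval_at(0)
  # pilot on the naive scale, then common-random-number slope
  beta <- (target_ratio - 1) * null_fit[["conc"]]
  if (beta == 0) beta <- 0.1
  cur <- eval_at(beta)
  lambda <- (cur[["obs"]] - null_fit[["obs"]]) / beta
  if (!is.finite(lambda) || lambda <= 0.05) lambda <- 1
  for (i in seq_len(max_iter)) {
    residual <- target_ratio * cur[["conc"]] - cur[["obs"]]
    if (abs(residual) < tol) break
    beta <- beta + residual / lambda
    cur <- eval_at(beta)
  }
  config$beta_vol[] <- 0
  config$beta_vol[[outcome]] <- beta
  config
}
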