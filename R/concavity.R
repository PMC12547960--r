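#' Fit the month-level income-to-health dose-response
#'
#' Estimates the best-fitting (possibly non-linear) relationship between
#' monthly income and a health outcome at the month level.  The default
#' backend is a penalized thin-plate regression spline (a GAM) with the
#' smoothness parameter chosen by REML, which captures the concavity of
#' the income-health relationship without assuming a functional form.
#' The `log_linear` backend is the simpler parametric alternative,
#' regressing the outcome on `log(income)`; it allows non-linearity but
#' captures the concavity less flexibly.
#'
#' @param panel A validated [monthly_panel] (the composite
#'   anxiety-depression outcome is formed on the fly).
#' @param outcome One of `"srh"`, `"anxdep"`, `"gad7"`, `"phq8"`.
#' @param backend `"penalized_spline"` (default) or `"log_linear"`.
#' @param k Spline basis dimension (default 10).
#' @param max_knots Maximum distinct incomes used to build the thin-plate
#'   basis (default 200); the eigen-decomposition over all distinct
#'   values is needless at these data sizes and this mgcv option
#'   subsamples them without changing the penalized fit appreciably.
#' @param min_rows Minimum month-level rows with both income and outcome
#'   (default 100).
#' @return An object of class `"dose_response"` with elements `backend`,
#'   `model`, `outcome`, `income_range`, and (spline backend) `edf` and
#'   `sp` (the smoothing parameter).
#' @export
fit_dose_response <- function(panel,
                              outcome = c("srh", "anxdep", "gad7", "phq8"),
                              backend = c("penalized_spline", "log_linear"),
                              k = 10, max_knots = 200, min_rows = 100) {
  outcome <- match.arg(outcome)
  backend <- match.arg(backend)
  d <- month_level_data(panel, outcome)
  if (nrow(d) < min_rows) {
    stop("only ", nrow(d), " month-level rows with income and ", outcome,
         " (need >= ", min_rows, ")", call. = FALSE)
  }
  if (backend == "penalized_spline") {
    model <- mgcv::gam(y ~ s(income, bs = "tp", k = k,
                             xt = list(max.knots = max_knots)),
                       data = d, method = "REML")
    if (!model$converged) {
      stop("smoothness selection did not converge; gcv/REML score ",
           format(model$gcv.ubre), call. = FALSE)
    }
    edf <- sum(model$edf)
    sp <- unname(model$sp)
  } else {
    model <- stats::lm(y ~ log(income), data = d)
    edf <- 2
    sp <- NA_real_
  }
  out <- list(backend = backend, model = model, outcome = outcome,
              income_range = range(d$income), n = nrow(d),
              k = k, edf = edf, sp = sp)
  class(out) <- "dose_response"
  out
}

month_level_data <- function(panel, outcome) {
  y <- if (outcome == "anxdep") {
    anxdep_composite(panel$gad7, panel$phq8)
  } else {
    panel[[outcome]]
  }
  d <- data.frame(person_id = panel$person_id, income = panel$income, y = y)
  d[stats::complete.cases(d[, c("income", "y")]), , drop = FALSE]
}

#' Predict from a fitted dose-response
#'
#' @param object A `"dose_response"` fit.
#' @param income Numeric vector of incomes (euros).
#' @param ... Unused.
#' @return Predicted outcome values.
#' @export
predict.dose_response <- function(object, income, ...) {
  as.numeric(stats::predict(object$model,
                            newdata = data.frame(income = income)))
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response of %s on monthly income (%s backend)\n",
              x$outcome, x$backend))
  cat(sprintf("  n = %d, income range %.0f-%.0f euros, edf %.2f\n",
              x$n, x$income_range[1], x$income_range[2], x$edf))
  invisible(x)
}

#' Derivative-based concavity check of a dose-response
#'
#' Evaluates first and second derivatives of the fitted curve at every
#' observed income value (central finite differences) and averages them.
#' A negative mean second derivative classifies the curve as downward
#' concave (the expected shape for positively-scored health outcomes),
#' a positive one as upward concave (expected for symptom scores where
#' higher is worse).
#'
#' Incomes outside the training range are clamped to it (the count is
#' reported).  The finite-difference step is
#' `1e-3 * (99th-percentile income - minimum income)`.
#'
#' @param fit A `"dose_response"`.
#' @param incomes Observed month-level incomes to evaluate at.
#' @return An object of class `"concavity_check"`: list with
#'   `mean_first_derivative` (outcome units per euro),
#'   `mean_second_derivative` (outcome units per euro squared),
#'   `orientation` (`"downward_concave"`, `"upward_concave"`, or
#'   `"not_concave"` when the mean second derivative is exactly 0),
#'   `step`, `n`, `n_clamped`.
#' @export
concavity_check <- function(fit, incomes) {
  stopifnot(inherits(fit, "dose_response"))
  incomes <- incomes[!is.na(incomes)]
  if (length(incomes) == 0) stop("no incomes to evaluate", call. = FALSE)
  lo <- fit$income_range[1]; hi <- fit$income_range[2]
  n_clamped <- sum(incomes < lo | incomes > hi)
  y <- pmin(pmax(incomes, lo), hi)
  h <- 1e-3 * (stats::quantile(y, 0.99, names = FALSE) - min(y))
  if (h <= 0) h <- 1e-3 * max(abs(y), 1)
  f_plus <- predict(fit, y + h)
  f_mid <- predict(fit, y)
  f_minus <- predict(fit, y - h)
  d1 <- (f_plus - f_minus) / (2 * h)
  d2 <- (f_plus - 2 * f_mid + f_minus) / h^2
  m2 <- mean(d2)
  orientation <- if (m2 < 0) "downward_concave"
    else if (m2 > 0) "upward_concave" else "not_concave"
  out <- list(mean_first_derivative = mean(d1),
              mean_second_derivative = m2,
              orientation = orientation,
              step = h, n = length(y), n_clamped = n_clamped)
  class(out) <- "concavity_check"
  out
}

#' @export
print.concavity_check <- function(x, ...) {
  cat(sprintf(
    "Concavity check over %d observed incomes (%d clamped to range):\n",
    x$n, x$n_clamped))
  cat(sprintf("  mean first derivative  %.3g per euro\n",
              x$mean_first_derivative))
  cat(sprintf("  mean second derivative %.3g per euro^2 (%.3g per kEUR^2)\n",
              x$mean_second_derivative, x$mean_second_derivative * 1e6))
  cat("  orientation:", x$orientation, "\n")
  invisible(x)
}

#' Concavity-predicted person-level outcomes
#'
#' Uses the fitted dose-response to predict the health score each person
#' should have had in each observed month based solely on their income in
#' that month, then averages across months.  The result is the health a
#' person would be expected to have given their income stream and the
#' observed curvature alone — the pure concavity-effect prediction, with
#' no direct effect of volatility.
#'
#' @param fit A `"dose_response"`.
#' @param panel The monthly panel (persons with no non-missing income are
#'   excluded, with a message).
#' @return Data frame `person_id`, `concavity_predicted`, `n_months`.
#' @export
concavity_predicted_outcomes <- function(fit, panel) {
  stopifnot(inherits(fit, "dose_response"))
  ok <- !is.na(panel$income)
  excluded <- setdiff(unique(panel$person_id), unique(panel$person_id[ok]))
  if (length(excluded)) {
    message(length(excluded), " person(s) with no income data excluded")
  }
  d <- panel[ok, ]
  pred <- predict(fit, d$income)
  agg <- tapply(pred, d$person_id, mean)
  data.frame(person_id = names(agg),
             concavity_predicted = as.numeric(agg),
             n_months = as.integer(table(d$person_id)[names(agg)]),
             stringsAsFactors = FALSE)
}

#' Observed-versus-concavity decomposition of the volatility association
#'
#' Compares the volatility coefficient from the model of the *observed*
#' outcome with the coefficient from the identical model of the
#' *concavity-predicted* outcome.  Their ratio is the headline statistic:
#' a ratio near 1 means the whole association is explained by the
#' concavity of the income-health curve (the Jensen mechanism); a ratio
#' substantially above 1 means volatility is associated with health over
#' and above what concavity can produce.
#'
#' @param observed A `"person_model"` of the observed outcome.
#' @param concavity_predicted A `"person_model"` of the
#'   concavity-predicted outcome, fitted with the same formula,
#'   transforms and persons.
#' @param tol Concavity coefficients smaller than `tol` in absolute value
#'   make the ratio undefined (`NA`); the excess is still returned.
#' @return An object of class `"concavity_decomposition"`: list with
#'   `observed_coef`, `concavity_coef`, `ratio`, `excess`,
#'   `sign_consistent` (FALSE flags an unstable ratio whose components
#'   disagree in sign), and the two n's.
#' @export
decomposition <- function(observed, concavity_predicted, tol = 1e-8) {
  stopifnot(inherits(observed, "person_model"),
            inherits(concavity_predicted, "person_model"))
  oc <- volatility_coef(observed)$estimate
  cc <- volatility_coef(concavity_predicted)$estimate
  ratio <- if (abs(cc) < tol) NA_real_ else oc / cc
  out <- list(observed_coef = oc,
              concavity_coef = cc,
              ratio = ratio,
              excess = oc - cc,
              sign_consistent = isTRUE(sign(oc) == sign(cc)),
              n_observed = observed$n_obs,
              n_concavity = concavity_predicted$n_obs)
  class(out) <- "concavity_decomposition"
  out
}

#' @export
print.concavity_decomposition <- function(x, ...) {
  cat("Volatility-association decomposition\n")
  cat(sprintf("  observed coefficient            %8.4f\n", x$observed_coef))
  cat(sprintf("  concavity-predicted coefficient %8.4f\n", x$concavity_coef))
  if (is.na(x$ratio)) {
    cat("  ratio undefined (concavity coefficient ~ 0)\n")
  } else {
    cat(sprintf("  ratio  %.2f%s\n", x$ratio,
                if (!x$sign_consistent) "  [unstable: signs differ]" else ""))
  }
  cat(sprintf("  excess %.4f (association beyond concavity)\n", x$excess))
  invisible(x)
}

#' Jensen gap of a concave curve
#'
#' For a person alternating between incomes `L` and `H` versus a person
#' steadily earning the midpoint `M = (L + H) / 2`, the average outcome of
#' the volatile person is `h* = (h(L) + h(H)) / 2`, which for a strictly
#' concave curve is strictly below `h(M)`.  The gap `h(M) - h*` is the
#' mechanical health cost of volatility produced by curvature alone.
#'
#' @param curve A function of income.
#' @param L,H Incomes in euros with `L < H`.
#' @return An object of class `"jensen_gap"`: list with `L`, `M`, `H`,
#'   `h_L`, `h_M`, `h_H`, `h_star` and `gap`.
#' @export
#' @examples
#' jensen_gap(log, 1000, 3000)$gap  # log(2000) - (log(1000)+log(3000))/2
jensen_gap <- function(curve, L, H) {
  stopifnot(is.function(curve), L < H)
  M <- (L + H) / 2
  vals <- c(h_L = curve(L), h_M = curve(M), h_H = curve(H))
  if (any(!is.finite(vals))) {
    stop("curve is not finite at L, M or H", call. = FALSE)
  }
  h_star <- (vals[["h_L"]] + vals[["h_H"]]) / 2
  out <- list(L = L, M = M, H = H,
              h_L = vals[["h_L"]], h_M = vals[["h_M"]], h_H = vals[["h_H"]],
              h_star = h_star, gap = vals[["h_M"]] - h_star)
  class(out) <- "jensen_gap"
  out
}

#' @export
print.jensen_gap <- function(x, ...) {
  cat(sprintf("Jensen gap: L=%g, M=%g, H=%g\n", x$L, x$M, x$H))
  cat(sprintf("  h(M) = %.4f, h* = (h(L)+h(H))/2 = %.4f, gap = %.4f\n",
              x$h_M, x$h_star, x$gap))
  invisible(x)
}
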