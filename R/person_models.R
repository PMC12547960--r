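#' Person-level model of averaged health on income level and volatility
#'
#' Ordinary least squares of a person-level mean outcome on
#' `log(mean_income)`, `log(volatility + eps0)`, age and gender
#' (categorical, "woman" reference).  This is the workhorse model for the
#' association between income volatility and health after adjusting for
#' the level of income: because coefficients in a multiple-variable model
#' are partial, the volatility coefficient estimates the impact of
#' volatility at a given income, orthogonal to income itself.
#'
#' Persons missing any model variable are dropped (model-level complete
#' case); the dropped count is recorded in the result.  Volatility can be
#' exactly zero, so its log transform uses a small offset `eps0`
#' (default 1 euro).
#'
#' @param aggregates A [aggregate_person()] data frame (any data frame
#'   with the referenced columns works, which lets callers model derived
#'   outcomes such as concavity-predicted health).
#' @param outcome Name of the outcome column, e.g. `"mean_srh"`,
#'   `"mean_anxdep"`, `"mean_gad7"`, `"mean_phq8"`.
#' @param log_terms Log-transform income and volatility (default `TRUE`,
#'   the standard analysis; `FALSE` uses raw euros).
#' @param eps0 Offset inside `log(volatility + eps0)`, euros.
#' @param covariates Character vector of adjustment covariates among
#'   `"age"` and `"gender"` (default both).
#' @param detrended Use the time-adjusted volatility statistic instead of
#'   the simple SD (default `FALSE`: the simple statistic is reported;
#'   the two are highly correlated and give qualitatively identical
#'   results).
#' @param min_cases Minimum complete cases required (default 20).
#' @return An object of class `"person_model"`: a list with elements
#'   `fit` (the `lm`), `table` (per-term estimate, 95% CI, p and partial
#'   eta-squared), `n_obs`, `n_dropped`, `r_squared`, `r_squared_adj`,
#'   `outcome`, `eps0`, and `data` (the complete-case model data with
#'   `person_id` and the untransformed volatility).
#' @export
fit_person_model <- function(aggregates, outcome = "mean_srh",
                             log_terms = TRUE, eps0 = 1,
                             covariates = c("age", "gender"),
                             detrended = FALSE, min_cases = 20) {
  stopifnot(eps0 > 0)
  if (!outcome %in% names(aggregates)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  if (length(covariates)) {
    covariates <- match.arg(covariates, c("age", "gender"),
                            several.ok = TRUE)
  } else {
    covariates <- character(0)
  }
  vol_col <- if (detrended) "volatility_detrended" else "volatility"
  d <- data.frame(
    person_id = aggregates$person_id,
    y = aggregates[[outcome]],
    mean_income = aggregates$mean_income,
    volatility = aggregates[[vol_col]],
    stringsAsFactors = FALSE
  )
  for (cv in covariates) d[[cv]] <- aggregates[[cv]]
  ok <- stats::complete.cases(d)
  n_dropped <- sum(!ok)
  d <- d[ok, , drop = FALSE]
  if (nrow(d) < min_cases) {
    stop("only ", nrow(d), " complete cases (need >= ", min_cases, ")",
         call. = FALSE)
  }
  if (log_terms) {
    d$income_term <- log(d$mean_income)
    d$vol_term <- log(d$volatility + eps0)
  } else {
    d$income_term <- d$mean_income
    d$vol_term <- d$volatility
  }
  if ("gender" %in% covariates) {
    d$gender <- factor(as.character(d$gender), levels = GENDER_LEVELS)
    d$gender <- droplevels(d$gender)
    if (nlevels(d$gender) < 2) {
      stop("collinearity: term 'gender' has a single observed level",
           call. = FALSE)
    }
  }
  rhs <- c("income_term", "vol_term", covariates)
  fml <- stats::reformulate(rhs, response = "y")
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; aliased term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  est <- stats::coef(fit)
  pvals <- sm$coefficients[, 4]

  rename <- c("(Intercept)" = "(Intercept)",
              income_term = "average_income",
              vol_term = "income_volatility",
              age = "age",
              genderman = "gender_man",
              genderother = "gender_other")
  terms <- names(est)
  labels <- ifelse(terms %in% names(rename), rename[terms], terms)

  pes <- partial_eta_sq_table(fit)
  pes_map <- stats::setNames(pes$partial_eta_sq, pes$term)
  anova_term <- c("(Intercept)" = NA, income_term = "income_term",
                  vol_term = "vol_term", age = "age",
                  genderman = "gender", genderother = "gender")

  tab <- data.frame(
    term = unname(labels),
    estimate = unname(est),
    ci_low = unname(ci[, 1]),
    ci_high = unname(ci[, 2]),
    p = unname(pvals),
    partial_eta_sq = unname(pes_map[anova_term[terms]]),
    stringsAsFactors = FALSE
  )
  out <- list(
    fit = fit,
    table = tab,
    outcome = outcome,
    eps0 = eps0,
    log_terms = log_terms,
    covariates = covariates,
    volatility_statistic = vol_col,
    n_obs = nrow(d),
    n_dropped = n_dropped,
    r_squared = sm$r.squared,
    r_squared_adj = sm$adj.r.squared,
    data = d
  )
  class(out) <- "person_model"
  out
}

# Type-III partial eta-squared for every model term.  With no
# interactions Type II and III sums of squares coincide, so treatment
# contrasts are safe here.  Degenerate fits with a zero residual sum of
# squares (exact data) fall back to direct drop-one-term refits.
partial_eta_sq_table <- function(fit) {
  a <- tryCatch(car::Anova(fit, type = "III"), error = function(e) NULL)
  if (!is.null(a)) {
    ss <- a[["Sum Sq"]]
    terms <- rownames(a)
    resid_ss <- ss[terms == "Residuals"]
    keep <- !terms %in% c("Residuals", "(Intercept)")
    return(data.frame(term = terms[keep],
                      partial_eta_sq = ss[keep] / (ss[keep] + resid_ss),
                      stringsAsFactors = FALSE))
  }
  d <- fit$model
  response <- names(d)[1]
  labs <- attr(stats::terms(fit), "term.labels")
  rss_full <- sum(stats::residuals(fit)^2)
  ss <- vapply(labs, function(tl) {
    remaining <- setdiff(labs, tl)
    fml <- if (length(remaining)) {
      stats::reformulate(remaining, response = response)
    } else {
      stats::reformulate("1", response = response)
    }
    sum(stats::residuals(stats::lm(fml, data = d))^2) - rss_full
  }, numeric(1))
  data.frame(term = labs,
             partial_eta_sq = ifelse(ss + rss_full > 0,
                                     ss / (ss + rss_full), 0),
             stringsAsFactors = FALSE)
}

#' Partial eta-squared of a model term
#'
#' Share of variance attributable to a term:
#' `SS_term / (SS_term + SS_residual)` with Type-III sums of squares.
#'
#' @param model A `"person_model"`.
#' @param term Term label as shown in `model$table$term`
#'   (e.g. `"income_volatility"`, `"average_income"`; the two gender rows
#'   share the single factor term, also addressable as `"gender"`).
#' @return A number in \[0, 1\].
#' @export
partial_eta_squared <- function(model, term) {
  stopifnot(inherits(model, "person_model"))
  if (term == "gender") {
    v <- model$table$partial_eta_sq[model$table$term == "gender_man"]
  } else {
    v <- model$table$partial_eta_sq[model$table$term == term]
  }
  if (length(v) == 0) {
    stop("term '", term, "' not found in model", call. = FALSE)
  }
  v[1]
}

#' Volatility coefficient of a person model
#'
#' Convenience accessor for the focal estimate.
#'
#' @param model A `"person_model"`.
#' @return Named list `estimate`, `ci_low`, `ci_high`, `p`.
#' @export
volatility_coef <- function(model) {
  stopifnot(inherits(model, "person_model"))
  row <- model$table[model$table$term == "income_volatility", ]
  list(estimate = row$estimate, ci_low = row$ci_low,
       ci_high = row$ci_high, p = row$p)
}

#' @export
print.person_model <- function(x, digits = 3, ...) {
  cat("Person-level model of", x$outcome,
      if (x$log_terms) "(income and volatility log-transformed)" else "",
      "\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$ci <- sprintf("%.*f to %.*f", digits, x$table$ci_low,
                    digits, x$table$ci_high)
  tab$p <- signif(tab$p, 2)
  tab$partial_eta_sq <- round(tab$partial_eta_sq, 3)
  print(tab[, c("term", "estimate", "ci", "p", "partial_eta_sq")],
        row.names = FALSE)
  cat(sprintf("Observations %d (dropped %d incomplete); R2 %.3f / adj %.3f\n",
              x$n_obs, x$n_dropped, x$r_squared, x$r_squared_adj))
  invisible(x)
}

#' Export a coefficient table to CSV
#'
#' @param model A `"person_model"` (or any object with a `table` data
#'   frame component).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(model, path) {
  tab <- model$table
  tab$n_obs <- model$n_obs
  tab$r_squared <- model$r_squared
  tab$r_squared_adj <- model$r_squared_adj
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
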