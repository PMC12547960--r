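#' Multilevel GAM of month-level health on income with person intercepts
#'
#' Month-level triangulation of the volatility question: each monthly
#' report is a data point, the month's income enters as a penalized
#' thin-plate spline (a level-1 smooth), age and gender are person-level
#' fixed effects, and each participant gets a Gaussian random intercept.
#' With `include_volatility = TRUE`, log income volatility is added as a
#' person-level (level-2) predictor, giving a direct inferential test of
#' whether volatility matters above and beyond the concave impact of the
#' income a person actually receives each month.
#'
#' The smooth and the random intercept are estimated jointly: the random
#' intercept is a penalized ridge term (`s(person, bs = "re")`) in the
#' same REML optimisation as the income spline, the standard
#' mixed-model-as-smooth formulation.
#'
#' @param panel A validated [monthly_panel].
#' @param outcome One of `"srh"`, `"anxdep"`, `"gad7"`, `"phq8"`.
#' @param include_volatility Add person-level `log(volatility + eps0)`.
#' @param eps0 Offset for the log-volatility transform, euros.
#' @param k Basis dimension of the income smooth.
#' @param detrended Use time-adjusted instead of simple volatility.
#' @param min_persons Minimum persons with >= 2 months (default 50).
#' @return Object of class `"multilevel_fit"`: list with `fixed` (term,
#'   estimate, 95% CI, p for the parametric fixed effects),
#'   `ranint_sd` (random-intercept SD), `ranint_var`, `smooth`
#'   (edf and p of the income smooth), `n_obs`, `n_persons`, `model`.
#' @export
fit_multilevel <- function(panel,
                           outcome = c("srh", "anxdep", "gad7", "phq8"),
                           include_volatility = TRUE, eps0 = 1, k = 10,
                           detrended = FALSE, min_persons = 50) {
  outcome <- match.arg(outcome)
  d <- month_level_data(panel, outcome)
  meta <- unique(panel[, c("person_id", "age", "gender")])
  d <- merge(d, meta, by = "person_id")
  if (include_volatility) {
    agg <- aggregate_person(panel)
    vol_col <- if (detrended) "volatility_detrended" else "volatility"
    agg$.vol <- agg[[vol_col]]
    if (all(is.na(agg$.vol))) {
      stop("volatility undefined for every person", call. = FALSE)
    }
    d$vol <- agg$.vol[match(d$person_id, agg$person_id)]
    d$vol_term <- log(d$vol + eps0)
  }
  keep_cols <- c("y", "income", "age", "gender",
                 if (include_volatility) "vol_term")
  d <- d[stats::complete.cases(d[, keep_cols]), , drop = FALSE]
  counts <- table(d$person_id)
  enough <- sum(counts >= 2)
  if (enough < min_persons) {
    stop("only ", enough, " persons with >= 2 complete months (need >= ",
         min_persons, ")", call. = FALSE)
  }
  d$person <- factor(d$person_id)
  d$gender <- droplevels(factor(as.character(d$gender),
                                levels = GENDER_LEVELS))
  rhs <- paste(c("s(income, bs = 'tp', k = k, xt = list(max.knots = 200))",
                 "age", "gender",
                 if (include_volatility) "vol_term",
                 "s(person, bs = 're')"),
               collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  model <- mgcv::bam(fml, data = d, method = "fREML", discrete = TRUE)
  if (!model$converged) {
    stop("multilevel REML fit did not converge; score ",
         format(model$gcv.ubre), call. = FALSE)
  }
  sm <- summary(model)
  pt <- sm$p.table
  zc <- stats::qnorm(0.975)
  rename <- c("(Intercept)" = "(Intercept)", age = "age",
              genderman = "gender_man", genderother = "gender_other",
              vol_term = "income_volatility")
  labels <- rownames(pt)
  labels <- ifelse(labels %in% names(rename), rename[labels], labels)
  fixed <- data.frame(term = unname(labels),
                      estimate = pt[, 1],
                      ci_low = pt[, 1] - zc * pt[, 2],
                      ci_high = pt[, 1] + zc * pt[, 2],
                      p = pt[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc_out <- utils::capture.output(vc <- mgcv::gam.vcomp(model))
  re_row <- grep("s(person)", rownames(vc), fixed = TRUE)
  ranint_sd <- unname(vc[re_row, "std.dev"])
  st <- sm$s.table
  sm_row <- grep("s(income)", rownames(st), fixed = TRUE)
  out <- list(fixed = fixed,
              ranint_sd = ranint_sd,
              ranint_var = ranint_sd^2,
              smooth = list(edf = unname(st[sm_row, "edf"]),
                            p = unname(st[sm_row, ncol(st)])),
              include_volatility = include_volatility,
              outcome = outcome, eps0 = eps0,
              n_obs = nrow(d), n_persons = nlevels(d$person),
              model = model)
  class(out) <- "multilevel_fit"
  out
}

#' @export
print.multilevel_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Multilevel GAM of %s: %d observations, %d persons\n",
    x$outcome, x$n_obs, x$n_persons))
  tab <- x$fixed
  tab$estimate <- round(tab$estimate, digits)
  tab$ci <- sprintf("%.*f to %.*f", digits, x$fixed$ci_low,
                    digits, x$fixed$ci_high)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "estimate", "ci", "p")], row.names = FALSE)
  cat(sprintf("  income smooth edf %.2f (p = %.2g)\n",
              x$smooth$edf, x$smooth$p))
  cat(sprintf("  random-intercept SD %.3f (variance %.3f)\n",
              x$ranint_sd, x$ranint_var))
  invisible(x)
}
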