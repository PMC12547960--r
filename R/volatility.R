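#' Simple income volatility
#'
#' Person-level income volatility operationalised as the sample standard
#' deviation (divisor `n - 1`) of the person's monthly income values.
#'
#' @param incomes Numeric vector of monthly incomes (euros), length >= 2,
#'   all finite and non-negative.
#' @return The sample standard deviation in euros.
#' @seealso [time_adjusted_volatility()] for the trend-adjusted variant.
#' @export
#' @examples
#' simple_volatility(c(1000, 1000, 1000, 1000))  # 0
#' simple_volatility(c(1, 2, 3))                 # 1
simple_volatility <- function(incomes) {
  incomes <- incomes[!is.na(incomes)]
  if (length(incomes) < 2) {
    stop("volatility undefined: need at least 2 income observations",
         call. = FALSE)
  }
  if (any(!is.finite(incomes)) || any(incomes < 0)) {
    stop("incomes must be finite and non-negative", call. = FALSE)
  }
  stats::sd(incomes)
}

#' Time-adjusted income volatility
#'
#' Standard deviation of the residuals from an ordinary least-squares
#' regression of income on month index, fitted for each person separately.
#' A person on a steady upward or downward income trajectory has a large
#' simple standard deviation even if month-to-month shocks are small; the
#' residual standard deviation isolates random shocks around the trend.
#'
#' The residual SD uses divisor `n - 1` by default so that it is directly
#' comparable with [simple_volatility()] (and is exactly equal to it when
#' the fitted slope is zero); `divisor = "n-2"` uses the residual degrees
#' of freedom instead.
#'
#' @param incomes Numeric vector of monthly incomes, length >= 3.
#' @param months Integer month indices, same length, strictly increasing.
#' @param divisor `"n-1"` (default) or `"n-2"`.
#' @return Residual standard deviation in euros.
#' @export
#' @examples
#' # a perfect linear ramp has zero adjusted volatility
#' time_adjusted_volatility(c(1000, 1100, 1200, 1300), 0:3)
time_adjusted_volatility <- function(incomes, months,
                                     divisor = c("n-1", "n-2")) {
  divisor <- match.arg(divisor)
  keep <- !is.na(incomes)
  incomes <- incomes[keep]
  months <- months[keep]
  n <- length(incomes)
  if (n < 3) {
    stop("time-adjusted volatility undefined: need at least 3 observations",
         call. = FALSE)
  }
  if (length(months) != n) stop("incomes and months differ in length",
                                call. = FALSE)
  if (any(diff(months) <= 0)) {
    stop("months must be strictly increasing", call. = FALSE)
  }
  res <- stats::lm.fit(cbind(1, months), incomes)$residuals
  df <- if (divisor == "n-1") n - 1 else n - 2
  sqrt(sum(res^2) / df)
}

#' Level-dependence of income volatility
#'
#' Pearson correlation and OLS regression of person-level income volatility
#' on mean income.  Volatility in absolute euros cannot be large when the
#' income itself is small, so the two are positively correlated across
#' persons; because the regression has a non-zero intercept, the
#' coefficient of variation does not remove this dependence, which is why
#' downstream models control for income level instead of using the CV.
#'
#' @param aggregates A person-aggregate data frame (see
#'   [aggregate_person()]) with columns `mean_income` and `volatility`, or
#'   any data frame with those columns.
#' @return A list with elements `correlation`, `slope`, `intercept`, `n`.
#' @export
volatility_level_dependence <- function(aggregates) {
  ok <- stats::complete.cases(aggregates[, c("mean_income", "volatility")])
  x <- aggregates$mean_income[ok]
  y <- aggregates$volatility[ok]
  if (length(x) < 2) stop("need at least 2 persons with defined volatility",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_
  } else {
    r <- stats::cor(x, y)
  }
  co <- stats::coef(stats::lm(y ~ x))
  list(correlation = r,
       slope = unname(co[2]),
       intercept = unname(co[1]),
       n = length(x))
}

#' Coefficient of variation of income
#'
#' `sd / mean` of a person's incomes.  Provided for visualisation only;
#' it is not statistically independent of income level in these data and
#' is excluded from inference paths.
#'
#' @param incomes Numeric vector of monthly incomes, length >= 2.
#' @return Dimensionless CV, or `NA` when the mean income is 0.
#' @export
income_cv <- function(incomes) {
  incomes <- incomes[!is.na(incomes)]
  m <- mean(incomes)
  if (m == 0) return(NA_real_)
  simple_volatility(incomes) / m
}
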