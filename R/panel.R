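#' @title Monthly panel data model
#' @description
#' A monthly panel is a long-format data frame with one row per
#' person-month and columns
#' `person_id, country, month_index, income, currency, srh, gad7, phq8,
#' age, gender`:
#'
#' * `person_id` — opaque identifier.
#' * `country` — `"UK"` or `"FR"`.
#' * `month_index` — integer study month, 0..11.
#' * `income` — euros actually received that month, `>= 0` (after
#'   conversion of GBP rows).
#' * `currency` — `"EUR"` or `"GBP"` (the currency the row was reported
#'   in; incomes are always stored in euros).
#' * `srh` — self-rated general health, 1 (very bad) to 9 (very good).
#' * `gad7` — GAD-7 anxiety total, integer 0..21.
#' * `phq8` — PHQ-8 depression total, integer 0..24.
#' * `age` — years, `>= 25`.
#' * `gender` — `"woman"`, `"man"` or `"other"`.
#'
#' Any of `income`, `srh`, `gad7`, `phq8` may be missing (`NA`) in a given
#' month; `(person_id, month_index)` pairs are unique.
#' @name monthly_panel
NULL

PANEL_COLUMNS <- c("person_id", "country", "month_index", "income",
                   "currency", "srh", "gad7", "phq8", "age", "gender")

GENDER_LEVELS <- c("woman", "man", "other")

#' Validate a monthly panel
#'
#' Checks the schema and range invariants of a monthly panel and returns
#' it with canonical column types.  Rows violating range invariants are
#' rejected: an error is thrown that names each offending row and field.
#'
#' @param panel Data frame with the columns described in [monthly_panel].
#' @return The validated panel (invisibly classed `"monthly_panel"`).
#' @export
validate_panel <- function(panel) {
  missing_cols <- setdiff(PANEL_COLUMNS, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel <- as.data.frame(panel)[PANEL_COLUMNS]
  panel$person_id <- as.character(panel$person_id)
  for (col in c("month_index", "income", "srh", "gad7", "phq8", "age")) {
    v <- panel[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(as.character(v)))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad)) {
        stop("non-numeric values in column '", col, "' at row(s): ",
             paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
      }
      panel[[col]] <- num
    }
  }
  panel$gender <- factor(as.character(panel$gender), levels = GENDER_LEVELS)
  panel$country <- factor(as.character(panel$country), levels = c("UK", "FR"))

  checks <- list(
    income = function(x) x >= 0,
    srh    = function(x) x >= 1 & x <= 9,
    gad7   = function(x) x >= 0 & x <= 21,
    phq8   = function(x) x >= 0 & x <= 24,
    age    = function(x) x >= 25,
    month_index = function(x) x >= 0 & x == floor(x)
  )
  problems <- character(0)
  for (col in names(checks)) {
    v <- panel[[col]]
    bad <- which(!is.na(v) & !checks[[col]](v))
    if (length(bad)) {
      problems <- c(problems, paste0(
        "column '", col, "' out of range at row(s) ",
        paste(utils::head(bad, 10), collapse = ", "),
        " (values ", paste(utils::head(v[bad], 10), collapse = ", "), ")"))
    }
  }
  if (length(problems)) {
    stop("panel rows rejected:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  dup <- duplicated(panel[c("person_id", "month_index")])
  if (any(dup)) {
    stop("duplicate (person_id, month_index) at row(s): ",
         paste(utils::head(which(dup), 10), collapse = ", "), call. = FALSE)
  }
  class(panel) <- c("monthly_panel", "data.frame")
  invisible(panel)
}

#' Read a monthly panel from CSV
#'
#' Reads a long-format UTF-8 CSV (one row per person-month, empty string =
#' missing), converts GBP incomes to euros using `gbp_to_eur`, and
#' validates every row.  Income cells may carry a currency symbol
#' (`£` or `€`), which overrides the `currency` column for that
#' row.
#'
#' @param path Path to the CSV file.
#' @param gbp_to_eur Positive conversion rate applied to GBP incomes
#'   (default 1.15; the conversion is a study convention, the rate is a
#'   configuration parameter).
#' @return A validated `monthly_panel` data frame with incomes in euros.
#' @export
read_panel <- function(path, gbp_to_eur = 1.15) {
  stopifnot(is.numeric(gbp_to_eur), gbp_to_eur > 0)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  missing_cols <- setdiff(PANEL_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("panel file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  inc <- raw$income
  cur <- toupper(ifelse(is.na(raw$currency), "EUR", raw$currency))
  sym_gbp <- grepl("£", inc)
  sym_eur <- grepl("€", inc)
  cur[sym_gbp] <- "GBP"
  cur[sym_eur] <- "EUR"
  inc_clean <- gsub("[£€,[:space:]]", "", inc)
  suppressWarnings(inc_num <- as.numeric(inc_clean))
  bad <- which(!is.na(inc) & is.na(inc_num))
  if (length(bad)) {
    stop("non-numeric income at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (values: ", paste(utils::head(inc[bad], 10), collapse = ", "), ")",
         call. = FALSE)
  }
  inc_num[cur == "GBP"] <- inc_num[cur == "GBP"] * gbp_to_eur
  raw$income <- inc_num
  raw$currency <- cur
  validate_panel(raw)
}

#' Write a monthly panel to CSV
#'
#' Inverse of [read_panel()]: writes the documented long-format CSV
#' dialect (empty string for missing).  Incomes are written in euros with
#' `currency` recording the original reporting currency, so
#' `read_panel(path, gbp_to_eur)` on the written file reproduces the
#' records exactly when called with any rate (no re-conversion happens
#' because incomes are stored in euros); `write_panel` therefore sets
#' `currency` to `"EUR"` on output.
#'
#' @param panel A validated monthly panel.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  out <- as.data.frame(panel)
  out$currency <- "EUR"
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Anxiety-depression composite
#'
#' The composite mental-health score: the average of the GAD-7 and PHQ-8
#' totals.  The two scales have very similar means and spreads, so they
#' contribute about equally; the composite ranges 0 to 22.5, higher =
#' worse mental health.  Missingness propagates: if either score is
#' missing the composite is missing (never imputed).
#'
#' @param gad7 GAD-7 total(s), 0..21.
#' @param phq8 PHQ-8 total(s), 0..24.
#' @return `(gad7 + phq8) / 2`, vectorised.
#' @export
#' @examples
#' anxdep_composite(21, 24)  # 22.5, the scale maximum
anxdep_composite <- function(gad7, phq8) {
  ok_g <- is.na(gad7) | (gad7 >= 0 & gad7 <= 21)
  ok_p <- is.na(phq8) | (phq8 >= 0 & phq8 <= 24)
  if (!all(ok_g)) stop("gad7 out of range [0, 21]", call. = FALSE)
  if (!all(ok_p)) stop("phq8 out of range [0, 24]", call. = FALSE)
  (gad7 + phq8) / 2
}

#' Aggregate a monthly panel to one row per person
#'
#' Computes, for each person, means of income and the health outcomes over
#' their observed (non-missing) months, plus the income-volatility
#' statistics.  Monthly anxiety-depression is formed with
#' [anxdep_composite()] before averaging, so months where only one of the
#' two scales was completed do not contribute to the composite mean.
#'
#' Persons with fewer than 2 income observations have `NA` volatility (and
#' are excluded by downstream model fits); the time-adjusted statistic
#' additionally needs 3 months.
#'
#' @param panel A validated monthly panel (or coercible data frame).
#' @param divisor Passed to [time_adjusted_volatility()].
#' @return A data frame classed `"person_aggregates"` with one row per
#'   person: `person_id, n_reports, mean_income, volatility,
#'   volatility_detrended, cv, mean_srh, mean_anxdep, mean_gad7,
#'   mean_phq8, age, gender, country`.
#' @export
aggregate_person <- function(panel, divisor = c("n-1", "n-2")) {
  divisor <- match.arg(divisor)
  panel <- validate_panel(panel)
  if (nrow(panel) == 0) {
    out <- data.frame(person_id = character(0))
    class(out) <- c("person_aggregates", "data.frame")
    return(out)
  }
  panel$anxdep <- anxdep_composite(panel$gad7, panel$phq8)
  panel <- panel[order(panel$person_id, panel$month_index), ]
  f <- factor(panel$person_id)
  ids <- levels(f)

  # group sums over non-missing values only
  gmean <- function(x) {
    n <- rowsum(as.numeric(!is.na(x)), f)
    s <- rowsum(ifelse(is.na(x), 0, x), f)
    out <- s / n
    out[n == 0] <- NA_real_
    as.numeric(out)
  }
  mean_income <- gmean(panel$income)

  # per-person income SD and residual SD from a regression on month
  # index, from group sums (equivalent to the per-person statistics in
  # simple_volatility() / time_adjusted_volatility())
  ok <- !is.na(panel$income)
  fo <- f[ok]
  y <- panel$income[ok]
  m <- panel$month_index[ok]
  gsum <- function(v) {
    rs <- rowsum(v, fo)
    out <- stats::setNames(numeric(length(ids)), ids)
    out[rownames(rs)] <- rs[, 1]
    unname(out)
  }
  n_inc <- gsum(rep(1, length(y)))
  sm <- gsum(m)
  # centre within person before forming sums of squares: the one-pass
  # formula cancels catastrophically for (near-)constant incomes
  idx <- match(as.character(fo), ids)
  yc <- y - (gsum(y) / n_inc)[idx]
  mc <- m - (sm / n_inc)[idx]
  ss_y <- gsum(yc^2)
  ss_m <- gsum(mc^2)
  s_my <- gsum(mc * yc)
  vol <- ifelse(n_inc >= 2, sqrt(ss_y / (n_inc - 1)), NA_real_)
  rss <- pmax(ss_y - ifelse(ss_m > 0, s_my^2 / ss_m, 0), 0)
  df_d <- if (divisor == "n-1") n_inc - 1 else n_inc - 2
  vol_d <- ifelse(n_inc >= 3, sqrt(rss / df_d), NA_real_)
  # volatility is zero iff all observed incomes are equal: snap values
  # at floating-point noise level to exact zero
  noise <- 1e-10 * pmax(abs(mean_income), 1)
  vol[!is.na(vol) & vol < noise] <- 0
  vol_d[!is.na(vol_d) & vol_d < noise] <- 0
  cv <- ifelse(n_inc >= 2 & mean_income != 0, vol / mean_income, NA_real_)

  first <- !duplicated(f)
  out <- data.frame(
    person_id = ids,
    n_reports = as.integer(table(f)),
    mean_income = mean_income,
    volatility = vol,
    volatility_detrended = vol_d,
    cv = cv,
    mean_srh = gmean(panel$srh),
    mean_anxdep = gmean(panel$anxdep),
    mean_gad7 = gmean(panel$gad7),
    mean_phq8 = gmean(panel$phq8),
    age = panel$age[first][match(ids, panel$person_id[first])],
    gender = panel$gender[first][match(ids, panel$person_id[first])],
    country = panel$country[first][match(ids, panel$person_id[first])],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("person_aggregates", "data.frame")
  out
}

#' Write person aggregates to CSV
#'
#' @param aggregates A `person_aggregates` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregates <- function(aggregates, path) {
  utils::write.csv(as.data.frame(aggregates), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}
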