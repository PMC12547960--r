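test_that("model recovers exactly known coefficients from noiseless data", {
  agg <- exact_aggregates(n = 80, seed = 21)
  agg$mean_srh <- 2 + 0.7 * log(agg$mean_income) -
    0.18 * log(agg$volatility + 1) + 0.01 * agg$age +
    0.3 * (agg$gender == "man") - 0.5 * (agg$gender == "other")
  m <- suppressWarnings(fit_person_model(agg, "mean_srh", eps0 = 1))
  tab <- m$table
  get <- function(term) tab$estimate[tab$term == term]
  expect_equal(get("average_income"), 0.7, tolerance = 1e-8)
  expect_equal(get("income_volatility"), -0.18, tolerance = 1e-8)
  expect_equal(get("age"), 0.01, tolerance = 1e-8)
  expect_equal(get("gender_man"), 0.3, tolerance = 1e-8)
  expect_equal(get("gender_other"), -0.5, tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-8)
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
})

test_that("partial eta-squared matches an extra-sum-of-squares oracle", {
  agg <- exact_aggregates(n = 120, seed = 22)
  agg$mean_srh <- 5 + 0.5 * log(agg$mean_income) -
    0.2 * log(agg$volatility + 1) + rnorm(120, 0, 0.8)
  m <- fit_person_model(agg, "mean_srh")
  d <- m$data
  full <- lm(y ~ income_term + vol_term + age + gender, data = d)
  rss_full <- sum(residuals(full)^2)
  drop_rss <- function(fml) sum(residuals(lm(fml, data = d))^2)
  oracle <- function(reduced) {
    ss <- drop_rss(reduced) - rss_full
    ss / (ss + rss_full)
  }
  expect_equal(partial_eta_squared(m, "income_volatility"),
               oracle(y ~ income_term + age + gender), tolerance = 1e-8)
  expect_equal(partial_eta_squared(m, "average_income"),
               oracle(y ~ vol_term + age + gender), tolerance = 1e-8)
  expect_equal(partial_eta_squared(m, "gender"),
               oracle(y ~ income_term + vol_term + age), tolerance = 1e-8)
  expect_error(partial_eta_squared(m, "not_a_term"), "not found")
  expect_true(all(m$table$partial_eta_sq >= 0 &
                    m$table$partial_eta_sq <= 1, na.rm = TRUE))
})

test_that("complete-case handling drops and counts incomplete persons", {
  agg <- exact_aggregates(n = 40, seed = 23)
  agg$mean_srh <- 5 - 0.2 * log(agg$volatility + 1)
  agg$age[1:4] <- NA
  agg$mean_srh[5] <- NA
  m <- suppressWarnings(fit_person_model(agg, "mean_srh"))
  expect_equal(m$n_obs, 35)
  expect_equal(m$n_dropped, 5)
  expect_error(suppressWarnings(fit_person_model(agg[1:10, ], "mean_srh")),
               "complete cases")
})

test_that("volatility estimate is insensitive to the log offset choice", {
  sim <- generate_panel(generator_config(n_persons = 300), seed = 24)
  agg <- aggregate_person(sim$panel)
  ests <- vapply(c(0.1, 1, 10), function(e) {
    volatility_coef(fit_person_model(agg, "mean_srh", eps0 = e))$estimate
  }, numeric(1))
  expect_true(all(sign(ests) == sign(ests[2])))
  # estimates shift smoothly with the offset, not wildly
  expect_lt(max(abs(ests - ests[2])), 0.5 * abs(ests[2]) + 0.05)
})

test_that("degenerate designs raise a collinearity error naming the term", {
  agg <- exact_aggregates(n = 40, seed = 25)
  agg$gender <- factor(rep("woman", 40),
                       levels = c("woman", "man", "other"))
  agg$mean_srh <- 5 - 0.2 * log(agg$volatility + 1)
  expect_error(fit_person_model(agg, "mean_srh"), "gender")
})

test_that("coefficients are invariant to affine recoding of age", {
  agg <- exact_aggregates(n = 80, seed = 26)
  agg$mean_srh <- 5 + 0.4 * log(agg$mean_income) -
    0.15 * log(agg$volatility + 1) + rnorm(80, 0, 0.5)
  m1 <- fit_person_model(agg, "mean_srh")
  agg2 <- agg
  agg2$age <- (agg2$age - 40) / 10
  m2 <- fit_person_model(agg2, "mean_srh")
  for (term in c("average_income", "income_volatility", "gender_man")) {
    expect_equal(m1$table$estimate[m1$table$term == term],
                 m2$table$estimate[m2$table$term == term],
                 tolerance = 1e-8)
  }
  expect_equal(fitted(m1$fit), fitted(m2$fit), tolerance = 1e-8)
})

test_that("focal estimates are null-calibrated when no effects exist", {
  # flat dose-response curves and zero direct/covariate effects: the
  # income and volatility CIs should cover zero at their nominal rate
  cfg <- generator_config(
    n_persons = 120,
    curve_srh = c(intercept = 6.1, slope = 0),
    curve_anxdep = c(intercept = 5.85, slope = 0),
    beta_vol = c(srh = 0, anxdep = 0),
    age_effect = c(srh = 0, anxdep = 0),
    man_effect = c(srh = 0, anxdep = 0)
  )
  cover <- vapply(1:40, function(s) {
    agg <- aggregate_person(generate_panel(cfg, seed = 400 + s)$panel)
    tab <- fit_person_model(agg, "mean_srh")$table
    focal <- tab[tab$term %in% c("average_income", "income_volatility"), ]
    all(focal$ci_low <= 0 & 0 <= focal$ci_high)
  }, logical(1))
  # both-CIs-cover has nominal rate ~0.95^2 >= 0.90; 31/40 allows ~3 sd
  # of binomial noise below that
  expect_gte(sum(cover), 31)
})
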