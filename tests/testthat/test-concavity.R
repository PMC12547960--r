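test_that("Jensen gap is positive for concave curves, zero for linear", {
  # closed form for the logarithmic curve
  jg <- jensen_gap(log, 1000, 3000)
  expect_equal(jg$gap, log(2000) - (log(1000) + log(3000)) / 2)
  expect_equal(jg$M, 2000)
  # algebraic identity for the quadratic: gap = (H - L)^2 / 4
  set.seed(31)
  for (i in 1:10) {
    L <- runif(1, 100, 2000)
    H <- L + runif(1, 10, 4000)
    expect_equal(jensen_gap(function(y) -y^2, L, H)$gap, (H - L)^2 / 4)
    # strict concavity: gap > 0
    expect_gt(jensen_gap(sqrt, L, H)$gap, 0)
    expect_gt(jensen_gap(log, L, H)$gap, 0)
    # linearity: gap exactly 0
    expect_equal(jensen_gap(function(y) 2 + 3 * y, L, H)$gap, 0)
  }
  expect_error(jensen_gap(log, 3000, 1000))
  expect_error(jensen_gap(function(y) rep(NaN, length(y)), 1, 2),
               "not finite")
})

test_that("the spline reproduces a noiseless line with zero curvature", {
  set.seed(32)
  n <- 300
  income <- runif(n, 500, 5000)
  p <- data.frame(person_id = sprintf("P%03d", rep(1:75, 4)),
                  country = "UK", month_index = rep(0:3, each = 75),
                  income = income, currency = "EUR",
                  srh = 1 + income / 1000, gad7 = NA, phq8 = NA,
                  age = 30, gender = "woman")
  # zero residual variance makes the REML step search complain; the fit
  # itself is exact
  fit <- suppressWarnings(fit_dose_response(p, "srh"))
  expect_lt(max(abs(predict(fit, income) - (1 + income / 1000))), 1e-3)
  ck <- concavity_check(fit, income)
  expect_equal(ck$mean_first_derivative, 1e-3, tolerance = 1e-3)
  expect_lt(abs(ck$mean_second_derivative), 1e-9)
})

test_that("the spline recovers a logarithmic dose-response under noise", {
  set.seed(33)
  n <- 5000
  income <- rlnorm(n, 8, 0.5)
  truth <- 0.6 + 0.7 * log(income)
  noise_sd <- 0.5
  srh <- pmin(pmax(truth + rnorm(n, 0, noise_sd), 1), 9)
  p <- data.frame(person_id = sprintf("P%04d", rep(1:1250, 4)),
                  country = "UK", month_index = rep(0:3, each = 1250),
                  income = income, currency = "EUR", srh = srh,
                  gad7 = NA, phq8 = NA, age = 30, gender = "woman")
  fit <- fit_dose_response(p, "srh")
  mae <- mean(abs(predict(fit, income) - truth))
  expect_lt(mae, noise_sd)
  expect_equal(concavity_check(fit, income)$orientation, "downward_concave")
})

test_that("concavity check recovers the curvature of an exact parabola", {
  set.seed(34)
  income <- runif(400, 500, 5000)
  srh <- 9 - 8 * ((income - 2750) / 2250)^2
  p <- data.frame(person_id = sprintf("P%03d", rep(1:100, 4)),
                  country = "UK", month_index = rep(0:3, each = 100),
                  income = income, currency = "EUR", srh = srh,
                  gad7 = NA, phq8 = NA, age = 30, gender = "woman")
  fit <- fit_dose_response(p, "srh")
  ck <- concavity_check(fit, income)
  d2_true <- -16 / 2250^2
  expect_equal(ck$mean_second_derivative, d2_true, tolerance = 0.05)
  expect_equal(ck$orientation, "downward_concave")
})

test_that("log-linear backend is exact and has analytic derivatives", {
  set.seed(35)
  income <- rlnorm(600, 8, 0.5)
  srh <- pmin(pmax(1 + 0.6 * log(income) + rnorm(600, 0, 0.3), 1), 9)
  p <- data.frame(person_id = sprintf("P%03d", rep(1:150, 4)),
                  country = "UK", month_index = rep(0:3, each = 150),
                  income = income, currency = "EUR", srh = srh,
                  gad7 = NA, phq8 = NA, age = 30, gender = "woman")
  fit <- fit_dose_response(p, "srh", backend = "log_linear")
  co <- coef(fit$model)
  expect_equal(predict(fit, income), co[1] + co[2] * log(income),
               ignore_attr = TRUE, tolerance = 1e-12)
  ck <- concavity_check(fit, income)
  expect_equal(ck$mean_first_derivative, mean(co[2] / income),
               tolerance = 1e-3)
})

test_that("concavity-predicted means equal a predict-then-average oracle", {
  sim <- generate_panel(generator_config(n_persons = 80), seed = 36)
  fit <- fit_dose_response(sim$panel, "srh")
  cp <- concavity_predicted_outcomes(fit, sim$panel)
  for (pid in cp$person_id[c(1, 20, 60)]) {
    rows <- sim$panel[sim$panel$person_id == pid & !is.na(sim$panel$income), ]
    expect_equal(cp$concavity_predicted[cp$person_id == pid],
                 mean(predict(fit, rows$income)))
  }
  # constant income: predicted mean is exactly the curve value there
  pconst <- data.frame(person_id = "Z", country = "UK", month_index = 0:3,
                       income = 1500, currency = "EUR", srh = 5,
                       gad7 = NA, phq8 = NA, age = 30, gender = "woman")
  cpz <- concavity_predicted_outcomes(fit, validate_panel(pconst))
  expect_equal(cpz$concavity_predicted, predict(fit, 1500))
})

test_that("mean-preserving income spreads never raise the predicted mean", {
  # exactly concave backend, so the Jensen ordering must hold exactly
  set.seed(37)
  income <- rlnorm(600, 8, 0.5)
  srh <- pmin(pmax(1 + 0.6 * log(income) + rnorm(600, 0, 0.3), 1), 9)
  p <- data.frame(person_id = sprintf("P%03d", rep(1:150, 4)),
                  country = "UK", month_index = rep(0:3, each = 150),
                  income = income, currency = "EUR", srh = srh,
                  gad7 = NA, phq8 = NA, age = 30, gender = "woman")
  fit <- fit_dose_response(p, "srh", backend = "log_linear")
  for (i in 1:20) {
    x <- rlnorm(6, 7.5, 0.4)
    d <- runif(1, 0, min(x) * 0.9)
    xs <- x                            # mean-preserving spread: push the
    xs[which.min(x)] <- min(x) - d     # minimum down and the maximum up
    xs[which.max(x)] <- max(x) + d
    expect_lte(mean(predict(fit, xs)), mean(predict(fit, x)) + 1e-12)
  }
  # two persons, same mean income, one volatile: volatile one is lower
  steady <- mean(predict(fit, c(2000, 2000)))
  volatile <- mean(predict(fit, c(1000, 3000)))
  expect_lt(volatile, steady)
})

test_that("decomposition extracts coefficients and forms the ratio", {
  agg <- exact_aggregates(n = 60, seed = 38)
  li <- log(agg$mean_income)
  lv <- log(agg$volatility + 1)
  agg$y_obs <- 3 + 0.5 * li - 0.18 * lv
  agg$y_cp <- 1 + 0.5 * li - 0.06 * lv
  obs <- suppressWarnings(fit_person_model(agg, "y_obs"))
  cp <- suppressWarnings(fit_person_model(agg, "y_cp"))
  dec <- decomposition(obs, cp)
  expect_equal(dec$observed_coef, -0.18, tolerance = 1e-8)
  expect_equal(dec$concavity_coef, -0.06, tolerance = 1e-8)
  expect_equal(dec$ratio, 3, tolerance = 1e-7)
  expect_equal(dec$excess, -0.12, tolerance = 1e-8)
  expect_true(dec$sign_consistent)

  agg$y_obs2 <- 3 + 0.5 * li + 0.64 * lv
  agg$y_cp2 <- 1 + 0.5 * li + 0.16 * lv
  dec2 <- decomposition(suppressWarnings(fit_person_model(agg, "y_obs2")),
                        suppressWarnings(fit_person_model(agg, "y_cp2")))
  expect_equal(dec2$ratio, 4, tolerance = 1e-7)

  # concavity coefficient at zero: ratio undefined, excess still returned
  agg$y_flat <- 1 + 0.5 * li
  dec3 <- decomposition(obs, suppressWarnings(fit_person_model(agg, "y_flat")))
  expect_true(is.na(dec3$ratio))
  expect_equal(dec3$excess, -0.18, tolerance = 1e-7)
})

test_that("both backends agree that a direct effect pushes the ratio above 1", {
  sim <- generate_panel(generator_config(), seed = 39)
  agg <- aggregate_person(sim$panel)
  obs <- fit_person_model(agg, "mean_srh")
  for (bk in c("penalized_spline", "log_linear")) {
    fit <- fit_dose_response(sim$panel, "srh", backend = bk)
    cp <- concavity_predicted_outcomes(fit, sim$panel)
    agg$.cp <- cp$concavity_predicted[match(agg$person_id, cp$person_id)]
    aggc <- agg[agg$person_id %in% obs$data$person_id, ]
    dec <- decomposition(obs, fit_person_model(aggc, ".cp"))
    expect_gt(dec$ratio, 1)
  }
})
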