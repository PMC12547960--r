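test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n_persons = 60)
  s1 <- generate_panel(cfg, seed = 71)
  s2 <- generate_panel(cfg, seed = 71)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$truth$persons, s2$truth$persons)
  s3 <- generate_panel(cfg, seed = 72)
  expect_false(identical(s1$panel$income, s3$panel$income))
})

test_that("degenerate config produces constant incomes and zero volatility", {
  cfg <- generator_config(n_persons = 20, sigma_eps = c(srh = 0, anxdep = 0),
                          trend_sd = 0, vol_meanlog = -Inf, vol_sdlog = 0,
                          beta_vol = c(srh = 0, anxdep = 0),
                          outcome_missing = 0, covariate_missing = 0)
  sim <- generate_panel(cfg, seed = 73)
  agg <- aggregate_person(sim$panel)
  expect_true(all(agg$volatility == 0, na.rm = TRUE))
  expect_true(all(agg$volatility_detrended == 0, na.rm = TRUE))
  per_person_range <- tapply(sim$panel$income, sim$panel$person_id,
                             function(x) diff(range(x)))
  expect_true(all(per_person_range == 0))
})

test_that("emitted records satisfy the panel invariants", {
  sim <- generate_panel(generator_config(n_persons = 150), seed = 74)
  p <- sim$panel
  expect_true(all(p$income >= 0))
  expect_true(all(p$srh >= 1 & p$srh <= 9, na.rm = TRUE))
  expect_true(all(p$gad7 >= 0 & p$gad7 <= 21, na.rm = TRUE))
  expect_true(all(p$phq8 >= 0 & p$phq8 <= 24, na.rm = TRUE))
  expect_true(all(p$age >= 25, na.rm = TRUE))
  expect_false(any(duplicated(p[c("person_id", "month_index")])))
  expect_s3_class(validate_panel(p), "monthly_panel")
})

test_that("the default panel matches its own descriptive targets", {
  sim <- generate_panel(generator_config(), seed = 1)
  agg <- aggregate_person(sim$panel)
  # mean income within 2 SE of the 3430-euro target
  se <- 1720 / sqrt(nrow(agg))
  expect_lt(abs(mean(agg$mean_income) - 3430), 2 * se)
  # GAD/PHQ person-mean correlation inside the Fisher-z band of 0.86
  ok <- complete.cases(agg$mean_gad7, agg$mean_phq8)
  r <- cor(agg$mean_gad7[ok], agg$mean_phq8[ok])
  band <- tanh(atanh(0.86) + c(-1, 1) * qnorm(0.975) / sqrt(sum(ok) - 3))
  expect_gt(r, band[1])
  expect_lt(r, band[2])
  # reporting pattern: about 10 of 12 months, strongly heterogeneous
  expect_gt(mean(agg$n_reports), 9)
  expect_gt(sd(agg$n_reports), 2)
})

test_that("implied concavity coefficient responds to curvature as it must", {
  # linear curve: no concavity, no implied association
  lin <- generator_config(n_persons = 300,
                          curve_srh = function(y) 2 + 0.001 * y,
                          beta_vol = c(srh = 0, anxdep = 0))
  sim_lin <- generate_panel(lin, seed = 75)
  io_lin <- implied_concavity_coefficient(sim_lin$truth, sim_lin$panel, "srh")
  expect_lt(abs(io_lin), 0.02)
  # doubling curvature (log slope) doubles the spread of curve values:
  # the implied magnitude must rise monotonically over the grid
  mags <- vapply(c(0.35, 0.7, 1.4), function(cc) {
    cfg <- generator_config(n_persons = 300,
                            curve_srh = c(intercept = 6.1 - 8 * cc,
                                          slope = cc),
                            beta_vol = c(srh = 0, anxdep = 0))
    sim <- generate_panel(cfg, seed = 76)
    abs(implied_concavity_coefficient(sim$truth, sim$panel, "srh"))
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("oracle and fitted concavity coefficient agree on a null panel", {
  res <- decomposition_rep(null_config(), seed = 77)
  expect_equal(res[["concavity"]], res[["oracle"]], tolerance = 0.4)
  expect_lt(abs(res[["concavity"]] - res[["oracle"]]), 0.05)
})

test_that("mismatched truth and panel are refused", {
  a <- generate_panel(generator_config(n_persons = 20), seed = 78)
  b <- generate_panel(generator_config(n_persons = 30), seed = 78)
  expect_error(
    implied_concavity_coefficient(a$truth, b$panel, "srh"),
    "same generation")
})

test_that("calibration drives the fitted ratio to its target", {
  # small-panel smoke test of the fixed-point calibration; the full
  # 200-replicate check lives in the acceptance suite
  cfg <- calibrate_beta_vol(generator_config(), 3, "srh",
                            reps = 6, seed = 790)
  expect_lt(cfg$beta_vol[["srh"]], 0)
  expect_equal(cfg$beta_vol[["anxdep"]], 0)
  rs <- vapply(1:6, function(s)
    decomposition_rep(cfg, seed = 800 + s)[["ratio"]], numeric(1))
  expect_gt(mean(rs), 1.5)
})
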