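test_that("single-cell deaths averted matches the closed-form PIF arithmetic", {
  # point masses 20 mmHg apart, rr20 = 4: pif = 0.75, 1000 deaths -> 750
  mort <- one_cell_mortality(deaths = 1000)
  shifts <- toy_shifts(
    base_mean = salt_to_sodium(10), base_sd = 0,
    cf_mean = salt_to_sodium(0.001), cf_sd = 0
  )
  # beta * delta_salt ~ 20 mmHg with beta = 2
  params <- flat_params(beta = 2, rr = 4)
  shifts$cf_mean_mg <- 0.4 # 0.001 g salt, nearly zero
  res <- deaths_averted(mort, shifts, params)
  expect_equal(res$cells$pif, 1 - 4^((0.001 - 10) / 10), tolerance = 1e-4)
  expect_equal(res$summary$deaths_averted[res$summary$level == "total"],
    1000 * 0.75,
    tolerance = 1e-2
  )
})

test_that("null parameters give zero impact and direction flips with the shift", {
  mort <- one_cell_mortality(deaths = 500)
  shifts <- toy_shifts()
  expect_equal(
    deaths_averted(mort, shifts, flat_params(beta = 0, rr = 2))$cells$pif, 0
  )
  expect_equal(
    deaths_averted(mort, shifts, flat_params(beta = 1, rr = 1))$cells$pif, 0
  )
  # pif = 0 everywhere -> 0 averted
  same <- toy_shifts(cf_mean = 3000, cf_sd = 1200)
  expect_equal(
    deaths_averted(mort, same, flat_params())$summary$deaths_averted,
    rep(0, nrow(deaths_averted(mort, same, flat_params())$summary))
  )
  # counterfactual above baseline: negative averted deaths (excess)
  up <- toy_shifts(cf_mean = 3600, cf_sd = 1200)
  expect_lt(deaths_averted(mort, up, flat_params())$cells$deaths_averted, 0)
})

test_that("impact accounting conserves deaths cell by cell", {
  cfg <- synthetic_config(seed = 31)
  mort <- generate_demography(cfg)
  tab <- baseline_intake_table()
  res <- deaths_averted(mort, scenario_shift_table(tab, "b"), load_parameters())
  expect_equal(res$cells$deaths - res$cells$deaths_averted, res$cells$cf_deaths)
  expect_true(all(res$cells$pif <= 1))
  # totals aggregate the cells
  expect_equal(
    res$summary$deaths_averted[res$summary$level == "total"],
    sum(res$cells$deaths_averted)
  )
  expect_equal(
    sort(res$summary$deaths_averted[res$summary$level == "sex"]),
    sort(tapply(res$cells$deaths_averted, res$cells$sex, sum), decreasing = FALSE),
    ignore_attr = TRUE
  )
})

test_that("lowering the counterfactual mean strictly increases deaths averted", {
  mort <- generate_demography(synthetic_config(seed = 41))
  params <- load_parameters()
  cf_means <- c(2600, 2300, 2000, 1700)
  totals <- vapply(cf_means, function(m) {
    shifts <- toy_shifts(base_mean = 3000, base_sd = 1400,
                         cf_mean = m, cf_sd = 1400 * m / 3000)
    res <- deaths_averted(mort, shifts, params)
    res$summary$deaths_averted[res$summary$level == "total"]
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})

test_that("small shifts linearize to deaths x k x |delta_mu|", {
  mort <- one_cell_mortality(deaths = 10000, age_band = "60-64")
  params <- flat_params(beta = 1, rr = 2)
  k <- log(2) / 20
  for (dmu_salt in c(0.01, 0.005)) {
    shifts <- toy_shifts(
      base_mean = 3000, base_sd = 1200,
      cf_mean = 3000 - salt_to_sodium(dmu_salt),
      cf_sd = 1200 * (3000 - salt_to_sodium(dmu_salt)) / 3000
    )
    res <- deaths_averted(mort, shifts, params)
    got <- res$summary$deaths_averted[res$summary$level == "total"]
    expect_equal(got, 10000 * k * dmu_salt, tolerance = 0.15)
  }
})

test_that("unmapped mortality cells raise a hard error naming the cell", {
  mort <- one_cell_mortality()
  shifts <- toy_shifts()[toy_shifts()$sex == "female", ] # no male strata
  expect_error(
    deaths_averted(mort, shifts, flat_params()),
    "male/60-64/I20-25"
  )
})

test_that("analytic and quadrature engines agree on a full mortality table", {
  mort <- generate_demography(synthetic_config(seed = 51))
  tab <- baseline_intake_table()
  params <- load_parameters()
  a <- deaths_averted(mort, scenario_shift_table(tab, "c"), params, method = "analytic")
  q <- deaths_averted(mort, scenario_shift_table(tab, "c"), params, method = "quadrature")
  expect_equal(a$cells$pif, q$cells$pif, tolerance = 1e-9)
})

test_that("Monte Carlo UI collapses, reproduces, and brackets correctly", {
  mort <- generate_demography(synthetic_config(seed = 61))
  shifts <- toy_shifts(base_mean = 3000, base_sd = 1400, cf_mean = 2400, cf_sd = 1120)

  # zero parameter uncertainty: UI collapses onto the point estimate
  p0 <- flat_params(beta = 1, beta_se = 0, rr = 2, log_se = 0)
  res0 <- monte_carlo_ui(mort, shifts, p0, iterations = 200, seed = 1)
  tot <- res0$point$summary$deaths_averted[res0$point$summary$level == "total"]
  ui0 <- res0$ui[res0$ui$group == "total", ]
  expect_equal(ui0$lo, tot, tolerance = 1e-12)
  expect_equal(ui0$hi, tot, tolerance = 1e-12)

  # fixed seed: bit-identical UIs
  p1 <- flat_params(beta = 1, beta_se = 0.2, rr = 2, log_se = 0.1)
  r1 <- monte_carlo_ui(mort, shifts, p1, iterations = 500, seed = 42)
  r2 <- monte_carlo_ui(mort, shifts, p1, iterations = 500, seed = 42)
  expect_identical(r1$ui, r2$ui)

  # UI brackets the point estimate
  tot1 <- r1$point$summary$deaths_averted[r1$point$summary$level == "total"]
  ui1 <- r1$ui[r1$ui$group == "total", ]
  expect_lt(ui1$lo, tot1)
  expect_gt(ui1$hi, tot1)

  expect_error(monte_carlo_ui(mort, shifts, p1, iterations = 1), ">= 2")
})
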