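test_that("misreporting classification matches the EER ratio boundaries", {
  expect_equal(as.character(classify_misreporting(1400, 2000)), "under") # exactly 70%
  expect_equal(as.character(classify_misreporting(2900, 2000)), "over") # 145%
  expect_equal(as.character(classify_misreporting(2000, 2000)), "plausible")
  expect_equal(as.character(classify_misreporting(2840, 2000)), "plausible") # exactly 142%

  # partition property: every respondent lands in exactly one class
  set.seed(3)
  kcal <- runif(500, 800, 4000)
  eer <- runif(500, 1500, 3000)
  cls <- classify_misreporting(kcal, eer)
  expect_equal(length(cls), 500)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), 500)

  expect_error(classify_misreporting(2000, 0), "EER must be positive")
})

test_that("usual-intake decomposition recovers between-person spread on simulated data", {
  set.seed(101)
  n <- 2000
  between_sd <- 500
  within_sd <- 800
  usual <- rnorm(n, 3000, between_sd)
  days <- tibble::tibble(
    respondent_id = rep(paste0("r", 1:n), each = 2),
    day_index = rep(1:2, n),
    sodium_mg = rep(usual, each = 2) + rnorm(2 * n, 0, within_sd)
  )
  resp <- tibble::tibble(
    respondent_id = paste0("r", 1:n),
    sex = "male", age_group = "31-50", weight = 1
  )
  est <- estimate_usual_distribution(days, resp)
  expect_equal(est$mean_mg, 3000, tolerance = 0.02)
  expect_equal(est$sd_mg, between_sd, tolerance = 0.10) # within 10%
  expect_equal(est$n, n)
  expect_equal(est$n_repeat, n)
})

test_that("usual-intake estimation handles degenerate and single-day strata", {
  # identical intakes on both days: SD collapses to the floor, mean exact
  days <- tibble::tibble(
    respondent_id = rep(c("a", "b", "c"), each = 2),
    day_index = rep(1:2, 3),
    sodium_mg = rep(c(2500, 2500, 2500), each = 2)
  )
  resp <- tibble::tibble(
    respondent_id = c("a", "b", "c"),
    sex = "female", age_group = "19-30", weight = 1
  )
  est <- estimate_usual_distribution(days, resp, sd_floor = 1)
  expect_equal(est$mean_mg, 2500)
  expect_equal(est$sd_mg, 1)

  # single-day-only data: falls back to total SD with a warning
  one_day <- days[days$day_index == 1, ]
  one_day$sodium_mg <- c(2000, 2500, 3000)
  expect_warning(
    est1 <- estimate_usual_distribution(one_day, resp),
    "no repeat recalls"
  )
  expect_equal(est1$sd_mg, sd(c(2000, 2500, 3000)), tolerance = 1e-6)

  # one-person stratum is an error
  expect_error(
    estimate_usual_distribution(days[1:2, ], resp[1, ]),
    "Degenerate stratum"
  )
})

test_that("proportional scenario reproduces printed counterfactual means to 1 mg", {
  tab <- baseline_intake_table()
  adults <- tab[tab$sex %in% c("male", "female"), ]
  baseline <- tibble::tibble(
    sex = adults$sex, age_group = adults$age_group,
    mean_mg = adults$baseline_mean, sd_mg = adults$baseline_sd
  )
  pop_mean <- tab$baseline_mean[tab$sex == "all"] # 2758

  b <- build_proportional_scenario(baseline, 2000, population_baseline_mg = pop_mean)
  expect_equal(
    round(b$scenario_mean_mg[b$sex == "male" & b$age_group == "19-30"]),
    2163
  )
  c_ <- build_proportional_scenario(baseline, 1500, population_baseline_mg = pop_mean)
  expect_equal(
    round(c_$scenario_mean_mg[c_$sex == "female" & c_$age_group == "51-70"]),
    1342
  )
  # whole scenario columns agree with the published integers within 1 mg slack
  expect_true(all(abs(round(b$scenario_mean_mg) - adults$scenario_b_mean) <= 1))
  expect_true(all(abs(round(c_$scenario_mean_mg) - adults$scenario_c_mean) <= 1))
})

test_that("proportional scaling preserves CV and hits the population target", {
  set.seed(5)
  baseline <- tibble::tibble(
    sex = rep(c("male", "female"), each = 4),
    age_group = rep(dri_age_groups(), 2),
    mean_mg = runif(8, 1800, 3500),
    sd_mg = runif(8, 400, 1500)
  )
  w <- runif(8, 0.5, 4)
  scen <- build_proportional_scenario(baseline, 2000, weights = w)
  # CV preserved exactly per stratum
  expect_equal(
    scen$scenario_sd_mg / scen$scenario_mean_mg,
    baseline$sd_mg / baseline$mean_mg
  )
  # weighted mean of scaled means hits the target exactly
  expect_equal(weighted.mean(scen$scenario_mean_mg, w), 2000)

  # identity when target equals the baseline mean
  pm <- weighted.mean(baseline$mean_mg, w)
  ident <- build_proportional_scenario(baseline, pm, weights = w)
  expect_equal(ident$scenario_mean_mg, baseline$mean_mg)

  # target above baseline: warn and clamp
  expect_warning(
    up <- build_proportional_scenario(baseline, 2 * pm, weights = w),
    "clamped"
  )
  expect_equal(up$scenario_mean_mg, baseline$mean_mg)
})

test_that("reformulation scenario responds correctly to the food supply", {
  cfg <- synthetic_config(seed = 22, n_respondents = 600, n_products = 300,
                          n_categories = 12, fraction_above_target = 0)
  supply <- generate_food_supply(cfg)
  recalls <- generate_recalls(cfg, supply)
  noop <- build_reformulation_scenario(
    recalls$items, recalls$respondents,
    supply$products, supply$targets, supply$match_map, supply$generic
  )
  # nothing above target: scenario equals baseline
  expect_equal(noop$scenario_mean_mg, noop$mean_mg)

  cfg2 <- synthetic_config(seed = 23, n_respondents = 600, n_products = 300,
                           n_categories = 12, fraction_above_target = 1,
                           fraction_uncategorized = 0)
  supply2 <- generate_food_supply(cfg2)
  recalls2 <- generate_recalls(cfg2, supply2)
  scen <- build_reformulation_scenario(
    recalls2$items, recalls2$respondents,
    supply2$products, supply2$targets, supply2$match_map, supply2$generic
  )
  # every categorized product capped: every stratum mean strictly decreases
  expect_true(all(scen$scenario_mean_mg < scen$mean_mg))
})

test_that("SE-to-SD conversion matches the published derivation", {
  # the bundled table's SDs were derived from SEs and effective sample sizes
  expect_equal(se_to_sd(64, 882), 64 * sqrt(882))
  expect_error(se_to_sd(10, 0), "n > 0")
})
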