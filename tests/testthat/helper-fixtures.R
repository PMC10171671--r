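# Shared in-code fixtures for the test suite. Everything is built
# programmatically; no binary data.

toy_products <- function() {
  tibble::tibble(
    product_id = paste0("p", 1:5),
    category_id = c("soup", "soup", "bread", "bread", NA),
    sodium_mg_per_100g = c(900, 400, 700, 450, 1200)
  )
}

toy_targets <- function() {
  tibble::tibble(
    category_id = c("soup", "bread"),
    target_mg_per_100g = c(600, 500)
  )
}

toy_profiles <- function() {
  tibble::tibble(
    profile_id = c("soup_mix", "loaf", "fruit"),
    sodium_mg_per_100g = c(NA, NA, 5)
  )
}

toy_match_map <- function() {
  tibble::tibble(
    profile_id = c("soup_mix", "soup_mix", "loaf", "loaf"),
    product_id = c("p1", "p2", "p3", "p4")
  )
}

# a tiny two-stratum recall set with hand-computable intakes
toy_recalls <- function() {
  respondents <- tibble::tibble(
    respondent_id = paste0("r", 1:4),
    sex = c("male", "male", "female", "female"),
    age_group = "31-50",
    weight = c(1, 2, 1, 1)
  )
  items <- tibble::tibble(
    respondent_id = c("r1", "r1", "r2", "r3", "r4"),
    day_index = 1L,
    profile_id = c("soup_mix", "fruit", "loaf", "soup_mix", "fruit"),
    amount_g = c(100, 200, 50, 150, 400)
  )
  list(respondents = respondents, items = items)
}

# single-cell mortality table for engine contract tests
one_cell_mortality <- function(deaths = 1000, cause = "I20-25",
                               sex = "male", age_band = "60-64") {
  tibble::tibble(
    sex = sex, age_band = age_band, cause = cause,
    deaths = deaths, population = 1e6
  )
}

# a flat parameter set with controllable uncertainty, covering all causes
flat_params <- function(beta = 1, beta_se = 0, rr = 2, log_se = 0) {
  causes <- cvd_causes()$cause
  structure(
    list(
      version = 1L,
      beta = tibble::tibble(
        age_range = c("19-30", "31-50", "51-70", "71+"),
        slope = beta, se = beta_se, provenance = "test"
      ),
      rr20 = tibble::tibble(
        cause = causes, age_range = "20+",
        rr = rr, ci_lower = NA_real_, ci_upper = NA_real_,
        provenance = "test", log_se = log_se
      )
    ),
    class = "rr_parameter_set"
  )
}

# minimal shift table covering one or more strata
toy_shifts <- function(base_mean = 3000, base_sd = 1200,
                       cf_mean = 2400, cf_sd = 960) {
  tidyr::expand_grid(
    sex = c("male", "female"),
    age_group = dri_age_groups()
  ) |>
    dplyr::mutate(
      baseline_mean_mg = base_mean, baseline_sd_mg = base_sd,
      cf_mean_mg = cf_mean, cf_sd_mg = cf_sd
    )
}
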