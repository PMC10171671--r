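#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic inputs: the recall survey (sample
#' size, repeat-day fraction, within-person day-to-day variation), the
#' stratum structure with true usual-intake distributions (defaulting to the
#' bundled national baseline column), the branded food supply (product and
#' category counts, fraction of products exceeding their benchmark target),
#' and the demography/mortality table (all-CVD death totals by sex, log-linear
#' age gradient, cause mix).
#'
#' @param seed Integer seed; every generator consumes it deterministically.
#' @param n_respondents Number of recall respondents.
#' @param strata Tibble with `sex`, `age_group`, `share` (sampling share),
#'   `mean_mg`, `sd_mg` (true usual-intake mean/SD, sodium mg/d). Default:
#'   the eight adult DRI strata of the bundled baseline table, shares
#'   proportional to its sample sizes.
#' @param second_day_fraction Fraction of respondents with a second recall
#'   day (default 0.35).
#' @param within_cv Within-person day-to-day coefficient of variation of
#'   intake (lognormal multiplicative noise; default 0.4).
#' @param items_per_day Number of recall items a day's intake is decomposed
#'   into.
#' @param n_products,n_categories Size of the synthetic branded food supply.
#' @param fraction_above_target Fraction of categorized products whose
#'   density exceeds their category target (default 0.5).
#' @param fraction_uncategorized Fraction of products with no category.
#' @param cvd_deaths Named vector of annual all-CVD deaths by sex (defaults
#'   to the 2019 Canadian totals: 30,663 male, 27,813 female).
#' @param age_gradient Log-linear mortality age gradient per year of age
#'   (default 0.075, i.e. deaths per band multiply by ~1.45 each 5 years).
#' @param open_band_factor Extra weight on the open-ended 85+ band
#'   (default 2, approximating its wider age span).
#' @param cause_shares Named list (per sex) of death shares across the seven
#'   ICD-10 cause groups.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(seed = 1L,
                             n_respondents = 5000,
                             strata = NULL,
                             second_day_fraction = 0.35,
                             within_cv = 0.4,
                             items_per_day = 8,
                             n_products = 1000,
                             n_categories = 40,
                             fraction_above_target = 0.5,
                             fraction_uncategorized = 0.1,
                             cvd_deaths = c(male = 30663, female = 27813),
                             age_gradient = 0.075,
                             open_band_factor = 2,
                             cause_shares = NULL) {
  if (is.null(strata)) {
    tb <- baseline_intake_table()
    tb <- tb[tb$sex %in% c("male", "female"), ]
    strata <- tibble::tibble(
      sex = tb$sex, age_group = tb$age_group,
      share = tb$n / sum(tb$n),
      mean_mg = tb$baseline_mean, sd_mg = tb$baseline_sd
    )
  }
  if (is.null(cause_shares)) {
    cause_shares <- list(
      male = c(
        "I20-25" = 0.555, "I60-69" = 0.190, "I50" = 0.100, "I10-15" = 0.095,
        "I71" = 0.033, "I26" = 0.015, "I05-09" = 0.012
      ),
      female = c(
        "I20-25" = 0.450, "I60-69" = 0.235, "I50" = 0.130, "I10-15" = 0.138,
        "I71" = 0.020, "I26" = 0.015, "I05-09" = 0.012
      )
    )
  }
  cfg <- list(
    seed = as.integer(seed),
    n_respondents = n_respondents,
    strata = tibble::as_tibble(strata),
    second_day_fraction = second_day_fraction,
    within_cv = within_cv,
    items_per_day = items_per_day,
    n_products = n_products,
    n_categories = n_categories,
    fraction_above_target = fraction_above_target,
    fraction_uncategorized = fraction_uncategorized,
    cvd_deaths = cvd_deaths,
    age_gradient = age_gradient,
    open_band_factor = open_band_factor,
    cause_shares = cause_shares
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    cfg$n_respondents > 0, cfg$n_products > 0, cfg$n_categories > 0,
    cfg$items_per_day > 0,
    cfg$second_day_fraction >= 0, cfg$second_day_fraction <= 1,
    cfg$fraction_above_target >= 0, cfg$fraction_above_target <= 1,
    cfg$fraction_uncategorized >= 0, cfg$fraction_uncategorized <= 1,
    cfg$within_cv >= 0, cfg$age_gradient >= 0, cfg$open_band_factor > 0
  )
  check_columns(cfg$strata, c("sex", "age_group", "share", "mean_mg", "sd_mg"),
    what = "strata"
  )
  if (any(cfg$strata$mean_mg <= 0) || any(cfg$strata$sd_mg <= 0)) {
    stop("Stratum means and SDs must be positive", call. = FALSE)
  }
  if (any(cfg$cvd_deaths < 0)) stop("Death totals must be non-negative", call. = FALSE)
  if (sum(cfg$cvd_deaths) == 0) {
    stop("Death totals are all zero; mortality table would be empty", call. = FALSE)
  }
  for (s in names(cfg$cause_shares)) {
    sh <- cfg$cause_shares[[s]]
    if (abs(sum(sh) - 1) > 1e-6) {
      stop("cause_shares for ", s, " must sum to 1", call. = FALSE)
    }
    missing <- setdiff(cvd_causes()$cause, names(sh))
    if (length(missing)) {
      stop("cause_shares for ", s, " missing: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(cfg)
}

# lognormal parameters matching a target mean and SD
lognormal_pars <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic branded food supply with benchmark targets
#'
#' Per category, a benchmark sodium target is drawn; product densities are
#' drawn so that the configured fraction of categorized products exceeds
#' their target. A configurable fraction of products carries no category
#' (mimicking foods outside the benchmark list). Each category is linked to
#' one recall food profile through the match map; additional unmatched
#' generic profiles round out the recall food list.
#'
#' @param config A [synthetic_config()].
#' @return List with `products`, `targets`, `match_map` and `generic`
#'   (profile table), shaped for [cap_to_targets()], [aggregate_profiles()]
#'   and [daily_sodium()].
#' @export
generate_food_supply <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)

  targets <- tibble::tibble(
    category_id = sprintf("cat%03d", seq_len(config$n_categories)),
    target_mg_per_100g = stats::runif(config$n_categories, 200, 800)
  )

  n <- config$n_products
  uncat <- stats::runif(n) < config$fraction_uncategorized
  category <- ifelse(uncat, NA_character_,
    sample(targets$category_id, n, replace = TRUE)
  )
  target_of <- targets$target_mg_per_100g[match(category, targets$category_id)]
  above <- !uncat & stats::runif(n) < config$fraction_above_target
  density <- ifelse(
    uncat, stats::runif(n, 20, 700),
    ifelse(above,
      target_of * stats::runif(n, 1.05, 2.0),
      target_of * stats::runif(n, 0.30, 1.00)
    )
  )
  products <- tibble::tibble(
    product_id = sprintf("prod%05d", seq_len(n)),
    category_id = category,
    sodium_mg_per_100g = density
  )

  # one matched profile per category, linked to that category's products
  cat_products <- split(products$product_id[!uncat], category[!uncat])
  match_map <- dplyr::bind_rows(lapply(names(cat_products), function(cz) {
    tibble::tibble(
      profile_id = paste0("prof_", cz),
      product_id = cat_products[[cz]]
    )
  }))

  matched_profiles <- unique(match_map$profile_id)
  n_generic <- max(5, round(length(matched_profiles) * 0.25))
  generic <- tibble::tibble(
    profile_id = c(matched_profiles, sprintf("prof_gen%03d", seq_len(n_generic))),
    sodium_mg_per_100g = c(
      rep(NA_real_, length(matched_profiles)),
      stats::runif(n_generic, 5, 500)
    )
  )
  list(products = products, targets = targets, match_map = match_map, generic = generic)
}

#' Generate synthetic 24-h recall microdata
#'
#' Respondents are allocated to the configured strata; each person's usual
#' sodium intake is drawn from a lognormal distribution matching the
#' stratum's mean/SD, each recall day multiplies it by mean-one lognormal
#' within-person noise, and every respondent contributes day 1 with the
#' configured fraction contributing a second day. Day intakes are decomposed
#' into recall items priced at the supply's aggregate profile densities, so
#' summing the items reproduces the day's intake exactly. Reported energy
#' and EER columns support the misreporting classifier.
#'
#' @param config A [synthetic_config()].
#' @param supply Optional output of [generate_food_supply()]; generated from
#'   `config` when missing.
#' @return List with `respondents` (id, stratum, survey weight, usual
#'   intake, energy columns), `items` (recall items) and `profiles` (the
#'   baseline aggregate profile table items are priced at).
#' @export
generate_recalls <- function(config, supply = NULL) {
  validate_synthetic_config(config)
  if (is.null(supply)) supply <- generate_food_supply(config)
  base_profiles <- aggregate_profiles(
    supply$products, supply$match_map, supply$generic
  )
  usable <- base_profiles[base_profiles$sodium_mg_per_100g > 0, ]

  set.seed(config$seed + 1L)
  n <- config$n_respondents
  strata <- config$strata
  s_idx <- sample.int(nrow(strata), n, replace = TRUE, prob = strata$share)

  usual <- numeric(n)
  for (j in seq_len(nrow(strata))) {
    rows <- which(s_idx == j)
    if (!length(rows)) next
    lp <- lognormal_pars(strata$mean_mg[j], strata$sd_mg[j])
    usual[rows] <- stats::rlnorm(length(rows), lp$meanlog, lp$sdlog)
  }

  eer <- ifelse(strata$sex[s_idx] == "male",
    stats::rnorm(n, 2500, 220), stats::rnorm(n, 1950, 180)
  )
  respondents <- tibble::tibble(
    respondent_id = sprintf("resp%05d", seq_len(n)),
    sex = strata$sex[s_idx],
    age_group = strata$age_group[s_idx],
    weight = stats::rlnorm(n, -0.045, 0.3),
    usual_mg = usual,
    eer_kcal = pmax(eer, 1000),
    reported_kcal = pmax(eer, 1000) * stats::rlnorm(n, -0.02, 0.22)
  )

  has_day2 <- stats::runif(n) < config$second_day_fraction
  days <- tibble::tibble(
    respondent_id = c(respondents$respondent_id, respondents$respondent_id[has_day2]),
    day_index = c(rep(1L, n), rep(2L, sum(has_day2))),
    usual_mg = c(usual, usual[has_day2])
  )
  if (config$within_cv > 0) {
    wl <- lognormal_pars(1, config$within_cv)
    noise <- stats::rlnorm(nrow(days), wl$meanlog, wl$sdlog)
  } else {
    noise <- 1
  }
  days$sodium_mg <- days$usual_mg * noise

  m <- config$items_per_day
  n_days <- nrow(days)
  shares <- matrix(stats::rexp(n_days * m), n_days, m)
  shares <- shares / rowSums(shares)
  prof_idx <- matrix(
    sample.int(nrow(usable), n_days * m, replace = TRUE),
    n_days, m
  )
  items <- tibble::tibble(
    respondent_id = rep(days$respondent_id, each = m),
    day_index = rep(days$day_index, each = m),
    profile_id = usable$profile_id[as.vector(t(prof_idx))],
    item_sodium_mg = as.vector(t(shares)) * rep(days$sodium_mg, each = m)
  )
  dens <- usable$sodium_mg_per_100g[match(items$profile_id, usable$profile_id)]
  items$amount_g <- items$item_sodium_mg * 100 / dens
  items$item_sodium_mg <- NULL

  list(respondents = respondents, items = items, profiles = base_profiles)
}

#' Generate a synthetic population and CVD mortality table
#'
#' Deaths follow a log-linear age gradient per cause within each sex and are
#' scaled (largest-remainder rounding) so each sex hits its configured
#' all-CVD total exactly. Populations per band decline at older ages. The
#' defaults emulate the structure of national vital-statistics extracts:
#' sex x five-year band (20-24 through 85+) x seven ICD-10 CVD cause groups.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `sex`, `age_band`, `cause`, `deaths`, `population`.
#' @export
generate_demography <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed + 2L)
  bands <- mortality_age_bands()
  mid <- age_band_midpoint(bands)
  open <- !is.finite(vapply(bands, function(b) parse_age_range(b)[2], numeric(1)))
  band_w <- exp(config$age_gradient * (mid - mid[1]))
  band_w[open] <- band_w[open] * config$open_band_factor

  population <- round(1.3e6 * exp(-0.17 * pmax(0, (mid - 60) / 5)))

  out <- lapply(names(config$cvd_deaths), function(s) {
    shares <- config$cause_shares[[s]]
    grid <- tidyr::expand_grid(age_band = bands, cause = names(shares))
    w <- band_w[match(grid$age_band, bands)] * shares[grid$cause]
    exact <- config$cvd_deaths[[s]] * w / sum(w)
    deaths <- floor(exact)
    rem <- config$cvd_deaths[[s]] - sum(deaths)
    if (rem > 0) {
      top <- order(exact - deaths, decreasing = TRUE)[seq_len(rem)]
      deaths[top] <- deaths[top] + 1
    }
    tibble::tibble(
      sex = s, age_band = grid$age_band, cause = grid$cause,
      deaths = as.numeric(deaths),
      population = population[match(grid$age_band, bands)]
    )
  })
  dplyr::bind_rows(out)
}
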