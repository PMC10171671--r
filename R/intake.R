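#' Bundled national sodium intake summary table
#'
#' Published survey-weighted usual sodium intake summaries for Canadian
#' adults (2015 national nutrition survey linked to 2017 branded food
#' composition data): per sex x DRI age-group stratum, the baseline mean
#' (with SE and derived SD) and the counterfactual means/SDs for the
#' reformulation scenario (A, population target 2300 mg/d), the WHO
#' recommendation (B, 2000 mg/d) and the Adequate Intake (C, 1500 mg/d).
#' The `all`/`all` row is the full-population (all ages) summary whose mean
#' (2758 mg/d) anchors the proportional-scaling scenarios.
#'
#' @return Tibble mirroring the published table; all intake columns in
#'   mg/day sodium.
#' @export
baseline_intake_table <- function() {
  path <- system.file("extdata", "canada_sodium_intake_2015.csv",
    package = "sodiumcra", mustWork = TRUE
  )
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Classify energy misreporting against estimated energy requirements
#'
#' Respondents with reported calorie intake at or below 70% of their
#' estimated energy requirement (EER) are under-reporters; above 142%,
#' over-reporters; otherwise plausible reporters.
#'
#' @param reported_kcal Positive numeric vector of reported energy intakes.
#' @param eer_kcal Positive numeric vector of estimated energy requirements.
#' @return Factor with levels `under`, `plausible`, `over`.
#' @examples
#' classify_misreporting(c(1400, 2000, 2900), 2000)
#' @export
classify_misreporting <- function(reported_kcal, eer_kcal) {
  if (any(eer_kcal <= 0, na.rm = TRUE)) {
    stop("EER must be positive", call. = FALSE)
  }
  if (any(reported_kcal <= 0, na.rm = TRUE)) {
    stop("Reported energy must be positive", call. = FALSE)
  }
  ratio <- reported_kcal / eer_kcal
  cls <- ifelse(ratio <= 0.70, "under", ifelse(ratio > 1.42, "over", "plausible"))
  factor(cls, levels = c("under", "plausible", "over"))
}

#' Estimate stratum usual-intake distributions from repeat 24-h recalls
#'
#' A moment-based stand-in for full usual-intake methodology: the stratum
#' mean is the survey-weighted mean of person-level recall means, and the
#' usual (between-person) variance is estimated by subtracting the
#' within-person sampling contribution from the variance of person means:
#'
#' \deqn{\hat\sigma^2_b = \max(\widehat{Var}(\bar y_i) - \hat\sigma^2_w / \bar d,\; \mathrm{floor})}
#'
#' where \eqn{\hat\sigma^2_w} is half the mean squared difference between the
#' two recall days of repeat respondents and \eqn{\bar d} is the mean number
#' of recall days per person. If a stratum has no repeat respondents the
#' usual SD falls back to the total person-mean SD, with a warning.
#'
#' @param person_days Tibble with `respondent_id`, `day_index`, `sodium_mg`.
#' @param respondents Tibble with `respondent_id`, `sex`, `age_group` and
#'   optionally `weight` (defaults to 1).
#' @param sd_floor Lower bound on the usual SD, mg/day; guards degenerate
#'   strata where the decomposition goes non-positive (default 1).
#' @return Tibble with one row per stratum: `sex`, `age_group`, `n`,
#'   `n_repeat`, `mean_mg`, `sd_mg`, `se_mg`, `form = "normal"`.
#' @export
estimate_usual_distribution <- function(person_days, respondents, sd_floor = 1) {
  check_columns(person_days, c("respondent_id", "day_index", "sodium_mg"),
    what = "person_days"
  )
  check_columns(respondents, c("respondent_id", "sex", "age_group"),
    what = "respondents"
  )
  respondents <- tibble::as_tibble(respondents)
  if (is.null(respondents$weight)) respondents$weight <- 1

  person <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(person_days), .data$respondent_id),
    person_mean = mean(.data$sodium_mg),
    n_days = dplyr::n(),
    day_diff = if (dplyr::n() == 2) diff(.data$sodium_mg) else NA_real_,
    .groups = "drop"
  )
  person <- dplyr::inner_join(person, respondents, by = "respondent_id")

  groups <- split(person, interaction(person$sex, person$age_group, drop = TRUE))
  out <- lapply(groups, function(g) {
    n <- nrow(g)
    if (n < 2) {
      stop("Degenerate stratum (", g$sex[1], ", ", g$age_group[1],
        "): need at least 2 respondents",
        call. = FALSE
      )
    }
    w <- g$weight
    m <- stats::weighted.mean(g$person_mean, w)
    total_var <- sum(w * (g$person_mean - m)^2) / sum(w) * n / (n - 1)
    repeats <- !is.na(g$day_diff)
    n_repeat <- sum(repeats)
    if (n_repeat >= 2) {
      within_var <- stats::weighted.mean(g$day_diff[repeats]^2, w[repeats]) / 2
      mean_days <- stats::weighted.mean(g$n_days, w)
      usual_var <- max(total_var - within_var / mean_days, sd_floor^2)
    } else {
      warning("Stratum (", g$sex[1], ", ", g$age_group[1],
        ") has no repeat recalls; usual SD falls back to total SD",
        call. = FALSE
      )
      usual_var <- max(total_var, sd_floor^2)
    }
    tibble::tibble(
      sex = g$sex[1], age_group = g$age_group[1],
      n = n, n_repeat = n_repeat,
      mean_mg = m, sd_mg = sqrt(usual_var),
      se_mg = sqrt(total_var / n),
      form = "normal"
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$sex), .data$age_group)
}

#' Build a proportional-scaling counterfactual scenario
#'
#' For targets expressed at the population level, the scenario reduces every
#' stratum by the same proportion: the ratio `r = target / population
#' baseline mean` scales each stratum mean, and each SD is scaled by the same
#' factor so the coefficient of variation is preserved exactly.
#'
#' @param baseline Tibble with per-stratum `sex`, `age_group`, `mean_mg`,
#'   `sd_mg` (baseline usual intake, mg/day sodium).
#' @param population_target_mg Population mean sodium target, mg/day.
#' @param population_baseline_mg Population baseline mean the ratio is taken
#'   against. Defaults to the weighted mean of the stratum means (weights
#'   below); pass the published all-ages mean when mimicking the national
#'   analysis, where the anchor includes age groups outside the adult table.
#' @param weights Optional stratum population weights used when
#'   `population_baseline_mg` is not supplied.
#' @return `baseline` with scenario columns `scenario_mean_mg`,
#'   `scenario_sd_mg`, and the applied `ratio` as an attribute.
#' @export
build_proportional_scenario <- function(baseline, population_target_mg,
                                        population_baseline_mg = NULL,
                                        weights = NULL) {
  check_columns(baseline, c("sex", "age_group", "mean_mg", "sd_mg"), "baseline")
  stopifnot(population_target_mg > 0)
  baseline <- tibble::as_tibble(baseline)
  if (is.null(population_baseline_mg)) {
    if (is.null(weights)) weights <- rep(1, nrow(baseline))
    population_baseline_mg <- stats::weighted.mean(baseline$mean_mg, weights)
  }
  r <- population_target_mg / population_baseline_mg
  if (r > 1) {
    warning("Population target (", population_target_mg,
      ") is above the baseline mean (", round(population_baseline_mg),
      "); nothing to reduce, ratio clamped to 1",
      call. = FALSE
    )
    r <- 1
  }
  baseline$scenario_mean_mg <- baseline$mean_mg * r
  baseline$scenario_sd_mg <- baseline$sd_mg * r
  attr(baseline, "ratio") <- r
  baseline
}

#' Build the reformulation counterfactual scenario from recall microdata
#'
#' Reruns the intake pipeline on a reformulated food supply: product
#' densities are capped at their category targets, aggregate profiles are
#' rebuilt, per respondent-day sodium is recomputed, and the stratum
#' usual-intake distributions are re-estimated. Returned side by side with
#' the baseline distributions estimated from the uncapped supply.
#'
#' @param items Recall item table (see [daily_sodium()]).
#' @param respondents Respondent table (see [estimate_usual_distribution()]).
#' @param products,targets Product and benchmark-target tables
#'   (see [cap_to_targets()]).
#' @param match_map,generic Profile linkage inputs
#'   (see [aggregate_profiles()]).
#' @param sd_floor Passed to [estimate_usual_distribution()].
#' @return Tibble with per-stratum baseline `mean_mg`/`sd_mg` and
#'   `scenario_mean_mg`/`scenario_sd_mg`.
#' @export
build_reformulation_scenario <- function(items, respondents, products, targets,
                                         match_map, generic, sd_floor = 1) {
  base_profiles <- aggregate_profiles(products, match_map, generic)
  capped <- cap_to_targets(products, targets)
  ref_profiles <- aggregate_profiles(capped, match_map, generic)

  base <- estimate_usual_distribution(
    daily_sodium(items, base_profiles), respondents,
    sd_floor = sd_floor
  )
  scen <- estimate_usual_distribution(
    daily_sodium(items, ref_profiles), respondents,
    sd_floor = sd_floor
  )
  scen <- scen[, c("sex", "age_group", "mean_mg", "sd_mg")]
  names(scen)[3:4] <- c("scenario_mean_mg", "scenario_sd_mg")
  dplyr::left_join(base, scen, by = c("sex", "age_group"))
}

#' Convert a reported standard error to a usual-intake SD
#'
#' Mimics deriving distribution SDs from published SEs: `SD = SE x sqrt(n)`,
#' with `n` the effective (survey-weighted) sample size of the stratum.
#'
#' @param se Standard error of the stratum mean.
#' @param n Effective sample size.
#' @return Standard deviation on the same scale as `se`.
#' @export
se_to_sd <- function(se, n) {
  stopifnot(all(se >= 0), all(n > 0))
  se * sqrt(n)
}
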