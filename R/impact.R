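#' Build an exposure-shift table from a scenario intake table
#'
#' Extracts, for one scenario, the per-stratum baseline and counterfactual
#' usual-intake distribution (sodium mg/day) from either the bundled
#' published-table format (`baseline_mean`/`baseline_sd` plus
#' `scenario_<x>_mean`/`scenario_<x>_sd` columns) or the
#' `build_*_scenario()` output format (`mean_mg`/`sd_mg` plus
#' `scenario_mean_mg`/`scenario_sd_mg`).
#'
#' @param intake_table Scenario intake table.
#' @param scenario For the published-table format, which scenario block to
#'   read: `"a"`, `"b"` or `"c"`. Ignored for the builder format.
#' @return Tibble with `sex`, `age_group`, `baseline_mean_mg`,
#'   `baseline_sd_mg`, `cf_mean_mg`, `cf_sd_mg`.
#' @export
scenario_shift_table <- function(intake_table, scenario = c("a", "b", "c")) {
  tb <- tibble::as_tibble(intake_table)
  if (all(c("mean_mg", "scenario_mean_mg") %in% names(tb))) {
    out <- tibble::tibble(
      sex = tb$sex, age_group = tb$age_group,
      baseline_mean_mg = tb$mean_mg, baseline_sd_mg = tb$sd_mg,
      cf_mean_mg = tb$scenario_mean_mg, cf_sd_mg = tb$scenario_sd_mg
    )
  } else {
    scenario <- match.arg(scenario)
    cols <- paste0("scenario_", scenario, c("_mean", "_sd"))
    check_columns(tb, c("sex", "age_group", "baseline_mean", "baseline_sd", cols),
      what = "intake_table"
    )
    out <- tibble::tibble(
      sex = tb$sex, age_group = tb$age_group,
      baseline_mean_mg = tb$baseline_mean, baseline_sd_mg = tb$baseline_sd,
      cf_mean_mg = tb[[cols[1]]], cf_sd_mg = tb[[cols[2]]]
    )
  }
  out[out$sex %in% c("male", "female"), ]
}

# Resolve every mortality cell against the shift table and the parameter
# set; returns the cell table augmented with salt-unit distribution
# parameters and parameter indices (used by both the point estimate and the
# Monte Carlo engine).
prepare_impact_cells <- function(mortality, shifts, params) {
  check_columns(mortality, c("sex", "age_band", "cause", "deaths"), "mortality")
  check_columns(
    shifts,
    c("sex", "age_group", "baseline_mean_mg", "baseline_sd_mg", "cf_mean_mg", "cf_sd_mg"),
    "shifts"
  )
  cells <- tibble::as_tibble(mortality)
  assert_sex(cells$sex)
  if (any(cells$deaths < 0)) stop("Negative death counts", call. = FALSE)

  cells$midpoint <- age_band_midpoint(cells$age_band)
  cells$age_group <- band_to_dri_group(cells$age_band)
  cells <- dplyr::left_join(cells, tibble::as_tibble(shifts),
    by = c("sex", "age_group")
  )
  unmapped <- is.na(cells$baseline_mean_mg)
  if (any(unmapped)) {
    bad <- cells[unmapped, c("sex", "age_band", "cause")]
    stop(
      "Mortality cell(s) with no intake stratum: ",
      paste(utils::head(
        paste(bad$sex, bad$age_band, bad$cause, sep = "/"), 5
      ), collapse = ", "),
      call. = FALSE
    )
  }

  beta <- resolve_beta(params, cells$midpoint)
  rr <- resolve_rr20(params, cells$cause, cells$midpoint)
  cells$beta <- beta$slope
  cells$beta_range <- beta$age_range
  cells$rr20 <- rr$rr
  cells$rr_range <- rr$age_range
  # indices into the parameter tables, for correlated Monte Carlo draws
  cells$beta_idx <- match(cells$beta_range, params$beta$age_range)
  cells$rr_idx <- match(
    paste(cells$cause, cells$rr_range),
    paste(params$rr20$cause, params$rr20$age_range)
  )

  # internal computation in grams of salt per day
  cells$mu_b <- sodium_to_salt(cells$baseline_mean_mg)
  cells$sd_b <- sodium_to_salt(cells$baseline_sd_mg)
  cells$mu_cf <- sodium_to_salt(cells$cf_mean_mg)
  cells$sd_cf <- sodium_to_salt(cells$cf_sd_mg)
  cells
}

# Ratio E_cf[RR] / E_base[RR] for a matrix of k values (draws x cells) and
# per-cell (truncated) normal distribution parameters. Vectorized; `k` may
# also be a plain vector of one k per cell.
rr_expectation_ratio <- function(k, mu_b, sd_b, mu_cf, sd_cf, truncated = TRUE) {
  if (is.matrix(k)) {
    mu_b <- matrix(mu_b, nrow(k), ncol(k), byrow = TRUE)
    sd_b <- matrix(sd_b, nrow(k), ncol(k), byrow = TRUE)
    mu_cf <- matrix(mu_cf, nrow(k), ncol(k), byrow = TRUE)
    sd_cf <- matrix(sd_cf, nrow(k), ncol(k), byrow = TRUE)
  }
  ratio <- exp(k * (mu_cf - mu_b) + k^2 * (sd_cf^2 - sd_b^2) / 2)
  if (truncated) {
    ratio <- ratio *
      stats::pnorm(mu_cf / sd_cf + k * sd_cf) / stats::pnorm(mu_cf / sd_cf) *
      stats::pnorm(mu_b / sd_b) / stats::pnorm(mu_b / sd_b + k * sd_b)
  }
  ratio
}

#' Cause-, age- and sex-specific CVD deaths averted by an intake shift
#'
#' The comparative-risk-assessment core. Each mortality cell (sex x
#' five-year age band x ICD-10 cause group) is mapped to its intake stratum
#' by band midpoint, the potential impact fraction of the baseline ->
#' counterfactual intake shift is computed through the salt -> SBP -> CVD
#' pathway, and averted deaths are `deaths x PIF`. Counterfactual deaths
#' (`deaths - averted`) are carried per cell so the accounting is
#' conservative by construction.
#'
#' @param mortality Tibble with `sex`, `age_band`, `cause`, `deaths` (and
#'   optionally `population`).
#' @param shifts Exposure-shift table from [scenario_shift_table()] or
#'   [build_proportional_scenario()] / [build_reformulation_scenario()]
#'   piped through `scenario_shift_table()`.
#' @param params An `rr_parameter_set` from [load_parameters()].
#' @param truncated Zero-truncate the normal intake distributions
#'   (default `TRUE`, PRIME-style).
#' @param mean_shift_only If `TRUE`, apply only the mean shift and keep the
#'   baseline SD on the counterfactual side (for comparison with
#'   distribution-unaware engines).
#' @param method `"analytic"` (closed-form expectations, default) or
#'   `"quadrature"`.
#' @param reference_deaths Total reference-year CVD deaths used for the
#'   percentage; defaults to the total deaths in `mortality`.
#' @return An object of class `impact_result`: list with `cells` (per-cell
#'   tibble including `pif`, `deaths_averted`, `cf_deaths`) and `summary`
#'   (totals overall, by sex, by cause, and the under-75 subtotal, with
#'   `pct_of_reference`).
#' @export
deaths_averted <- function(mortality, shifts, params,
                           truncated = TRUE, mean_shift_only = FALSE,
                           method = c("analytic", "quadrature"),
                           reference_deaths = NULL) {
  method <- match.arg(method)
  cells <- prepare_impact_cells(mortality, shifts, params)
  if (mean_shift_only) cells$sd_cf <- cells$sd_b

  k <- log(cells$rr20) / 20 * cells$beta
  if (method == "analytic") {
    ratio <- rr_expectation_ratio(
      k, cells$mu_b, cells$sd_b, cells$mu_cf, cells$sd_cf,
      truncated = truncated
    )
  } else {
    ratio <- vapply(seq_len(nrow(cells)), function(i) {
      expected_rr(cells$mu_cf[i], cells$sd_cf[i], cells$beta[i], cells$rr20[i],
        truncated = truncated, method = "quadrature"
      ) /
        expected_rr(cells$mu_b[i], cells$sd_b[i], cells$beta[i], cells$rr20[i],
          truncated = truncated, method = "quadrature"
        )
    }, numeric(1))
  }
  cells$pif <- 1 - ratio
  cells$deaths_averted <- cells$deaths * cells$pif
  cells$cf_deaths <- cells$deaths - cells$deaths_averted

  structure(
    list(
      cells = cells,
      summary = summarise_impact_cells(cells, reference_deaths)
    ),
    class = "impact_result"
  )
}

summarise_impact_cells <- function(cells, reference_deaths = NULL) {
  if (is.null(reference_deaths)) reference_deaths <- sum(cells$deaths)
  under75 <- is.finite(vapply(cells$age_band, function(b) parse_age_range(b)[2], numeric(1))) &
    vapply(cells$age_band, function(b) parse_age_range(b)[2], numeric(1)) < 75

  total <- tibble::tibble(
    level = "total", group = "total",
    deaths = sum(cells$deaths),
    deaths_averted = sum(cells$deaths_averted)
  )
  by_sex <- dplyr::summarise(
    dplyr::group_by(cells, group = .data$sex),
    deaths = sum(.data$deaths),
    deaths_averted = sum(.data$deaths_averted),
    .groups = "drop"
  )
  by_sex <- dplyr::mutate(by_sex, level = "sex", .before = 1)
  by_cause <- dplyr::summarise(
    dplyr::group_by(cells, group = .data$cause),
    deaths = sum(.data$deaths),
    deaths_averted = sum(.data$deaths_averted),
    .groups = "drop"
  )
  by_cause <- dplyr::mutate(by_cause, level = "cause", .before = 1)
  u75 <- tibble::tibble(
    level = "under75", group = "under75",
    deaths = sum(cells$deaths[under75]),
    deaths_averted = sum(cells$deaths_averted[under75])
  )
  out <- dplyr::bind_rows(total, by_sex, by_cause, u75)
  out$pct_of_reference <- 100 * out$deaths_averted / reference_deaths
  attr(out, "reference_deaths") <- reference_deaths
  out
}

#' @export
print.impact_result <- function(x, ...) {
  tot <- x$summary[x$summary$level == "total", ]
  cat(
    "<impact_result>", nrow(x$cells), "cells;",
    sprintf("%.0f", tot$deaths_averted), "deaths averted",
    sprintf("(%.1f%% of reference-year CVD deaths)\n", tot$pct_of_reference)
  )
  invisible(x)
}

#' Monte Carlo uncertainty intervals for a scenario's deaths averted
#'
#' Propagates epidemiological parameter uncertainty: per iteration one slope
#' draw per age range (`beta ~ Normal(beta, se)`, negative draws truncated
#' at zero) and one log-RR draw per (cause, age-range) entry
#' (`log rr20 ~ Normal(log rr20, log_se)`), shared across sexes, then the
#' full impact computation is rerun. The 95% uncertainty interval is the
#' 2.5th/97.5th percentile of the iteration totals; runs are deterministic
#' under a fixed seed.
#'
#' @inheritParams deaths_averted
#' @param iterations Number of Monte Carlo iterations (default 10000).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `scenario_result`: list with `point` (the
#'   [deaths_averted()] result), `ui` (tibble of 2.5%/97.5% bounds for the
#'   total, each sex, each cause and the under-75 subtotal), `iterations`
#'   and `seed`.
#' @export
monte_carlo_ui <- function(mortality, shifts, params, iterations = 10000,
                           seed = NULL, truncated = TRUE,
                           mean_shift_only = FALSE, reference_deaths = NULL) {
  if (iterations < 2) stop("iterations must be >= 2", call. = FALSE)
  point <- deaths_averted(mortality, shifts, params,
    truncated = truncated, mean_shift_only = mean_shift_only,
    reference_deaths = reference_deaths
  )
  cells <- point$cells
  if (mean_shift_only) cells$sd_cf <- cells$sd_b
  if (!is.null(seed)) set.seed(seed)

  n_beta <- nrow(params$beta)
  n_rr <- nrow(params$rr20)
  beta_draws <- matrix(
    stats::rnorm(iterations * n_beta, mean = rep(params$beta$slope, each = iterations),
      sd = rep(params$beta$se, each = iterations)
    ),
    iterations, n_beta
  )
  beta_draws[beta_draws < 0] <- 0
  logrr_draws <- matrix(
    stats::rnorm(iterations * n_rr, mean = rep(log(params$rr20$rr), each = iterations),
      sd = rep(params$rr20$log_se, each = iterations)
    ),
    iterations, n_rr
  )

  k <- (logrr_draws[, cells$rr_idx, drop = FALSE] / 20) *
    beta_draws[, cells$beta_idx, drop = FALSE]
  ratio <- rr_expectation_ratio(
    k, cells$mu_b, cells$sd_b, cells$mu_cf, cells$sd_cf,
    truncated = truncated
  )
  averted <- sweep(1 - ratio, 2, cells$deaths, "*") # iterations x cells

  groups <- list(total = rep(TRUE, nrow(cells)))
  for (s in unique(cells$sex)) groups[[s]] <- cells$sex == s
  for (cz in unique(cells$cause)) groups[[cz]] <- cells$cause == cz
  hi_age <- vapply(cells$age_band, function(b) parse_age_range(b)[2], numeric(1))
  groups[["under75"]] <- is.finite(hi_age) & hi_age < 75

  ind <- vapply(groups, as.numeric, numeric(nrow(cells)))
  totals <- averted %*% ind # iterations x groups
  qs <- apply(totals, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)

  level <- ifelse(names(groups) %in% c("male", "female"), "sex",
    ifelse(names(groups) %in% unique(cells$cause), "cause", names(groups))
  )
  ui <- tibble::tibble(
    level = level,
    group = names(groups),
    lo = unname(qs[1, ]),
    hi = unname(qs[2, ])
  )

  structure(
    list(point = point, ui = ui, iterations = iterations, seed = seed),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  tot <- x$point$summary[x$point$summary$level == "total", ]
  ui <- x$ui[x$ui$group == "total", ]
  cat(sprintf(
    "<scenario_result> %.0f deaths averted (95%% UI %.0f-%.0f; %d iterations)\n",
    tot$deaths_averted, ui$lo, ui$hi, x$iterations
  ))
  invisible(x)
}
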