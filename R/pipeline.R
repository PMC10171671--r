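#' Round half away from zero
#'
#' Printed percentages use half-up rounding (2.35 -> 2.4), unlike base R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render the cross-scenario summary table
#'
#' One row per sex (plus the total) and scenario: point estimate of deaths
#' averted or delayed, its 95% uncertainty interval, and the percentage of
#' reference-year CVD deaths (half-up rounded to one decimal).
#'
#' @param results Named list of `scenario_result` objects (names are the
#'   scenario labels, e.g. `A`, `B`, `C`).
#' @return Tibble with `scenario`, `sex`, `deaths_averted`, `ui_lo`, `ui_hi`,
#'   `pct_of_reference`.
#' @export
render_summary <- function(results) {
  if (!length(results)) stop("Need at least one scenario result", call. = FALSE)
  if (is.null(names(results))) names(results) <- LETTERS[seq_along(results)]
  rows <- lapply(names(results), function(nm) {
    res <- results[[nm]]
    summ <- res$point$summary
    ref <- attr(summ, "reference_deaths")
    keep <- summ[summ$level %in% c("sex", "total"), ]
    ui <- res$ui[match(keep$group, res$ui$group), ]
    tibble::tibble(
      scenario = nm,
      sex = keep$group,
      deaths_averted = keep$deaths_averted,
      ui_lo = ui$lo,
      ui_hi = ui$hi,
      pct_of_reference = round_half_up(100 * keep$deaths_averted / ref, 1)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$sex <- factor(out$sex, levels = c("male", "female", "total"))
  dplyr::arrange(out, .data$scenario, .data$sex)
}

write_stage_csv <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

read_stage_csv <- function(out_dir, name, stage) {
  path <- file.path(out_dir, name)
  if (!file.exists(path)) {
    stop("Stage `", stage, "` failed: required input ", name,
      " not found in ", out_dir,
      call. = FALSE
    )
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run the full sodium-reduction impact pipeline on synthetic data
#'
#' Orchestrates the stages `reformulate` -> `build-scenarios` ->
#' `estimate-impact` -> `report` against a synthetic input set generated
#' from `config`, writing every intermediate and final table as CSV plus a
#' run manifest into `out_dir`. Individual stages can be rerun by passing a
#' subset of `stages`; later stages read earlier stages' CSVs from
#' `out_dir`.
#'
#' @param config A [synthetic_config()] describing the synthetic inputs.
#' @param out_dir Output directory (created if needed).
#' @param parameter_file Path to the dose-response parameter file.
#' @param iterations Monte Carlo iterations for the uncertainty intervals.
#' @param targets_mg Named vector of population sodium targets for the
#'   proportional scenarios (defaults to B = 2000, C = 1500 mg/d).
#' @param stages Which stages to run, in order.
#' @return Invisibly, a list with the scenario intake table, the per-scenario
#'   `scenario_result`s, the summary tibble and the manifest path.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         out_dir,
                         parameter_file = default_parameter_file(),
                         iterations = 2000,
                         targets_mg = c(B = 2000, C = 1500),
                         stages = c("reformulate", "build-scenarios", "estimate-impact", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!file.exists(parameter_file)) {
    stop("Stage `estimate-impact` failed: parameter file not found: ",
      parameter_file,
      call. = FALSE
    )
  }
  t0 <- Sys.time()
  results <- list()

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("Stage `", stage, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if ("reformulate" %in% stages) {
    run_stage("reformulate", {
      supply <- generate_food_supply(config)
      recalls <- generate_recalls(config, supply)
      mortality <- generate_demography(config)
      scen_a <- build_reformulation_scenario(
        recalls$items, recalls$respondents,
        supply$products, supply$targets, supply$match_map, supply$generic
      )
      write_stage_csv(supply$products, out_dir, "products.csv")
      write_stage_csv(supply$targets, out_dir, "targets.csv")
      write_stage_csv(recalls$items, out_dir, "recall_items.csv")
      write_stage_csv(recalls$respondents, out_dir, "respondents.csv")
      write_stage_csv(mortality, out_dir, "mortality.csv")
      write_stage_csv(scen_a, out_dir, "scenario_a_intake.csv")
      message(
        "reformulate: ", nrow(supply$products), " products, ",
        nrow(recalls$items), " recall items -> ", nrow(scen_a), " strata"
      )
    })
  }

  if ("build-scenarios" %in% stages) {
    run_stage("build-scenarios", {
      scen_a <- read_stage_csv(out_dir, "scenario_a_intake.csv", "build-scenarios")
      baseline <- scen_a[, c("sex", "age_group", "n", "mean_mg", "sd_mg")]
      pop_mean <- stats::weighted.mean(baseline$mean_mg, baseline$n)
      tab <- tibble::tibble(
        sex = baseline$sex, age_group = baseline$age_group, n = baseline$n,
        baseline_mean = baseline$mean_mg, baseline_sd = baseline$sd_mg,
        scenario_a_mean = scen_a$scenario_mean_mg,
        scenario_a_sd = scen_a$scenario_sd_mg
      )
      for (nm in names(targets_mg)) {
        prop <- build_proportional_scenario(
          baseline, targets_mg[[nm]],
          population_baseline_mg = pop_mean
        )
        tab[[paste0("scenario_", tolower(nm), "_mean")]] <- prop$scenario_mean_mg
        tab[[paste0("scenario_", tolower(nm), "_sd")]] <- prop$scenario_sd_mg
      }
      write_stage_csv(tab, out_dir, "scenario_intake_table.csv")
      message(
        "build-scenarios: population baseline mean ",
        round(pop_mean), " mg/d; scenarios: a, ",
        paste(tolower(names(targets_mg)), collapse = ", ")
      )
    })
  }

  scenario_labels <- c("a", tolower(names(targets_mg)))
  if ("estimate-impact" %in% stages) {
    run_stage("estimate-impact", {
      tab <- read_stage_csv(out_dir, "scenario_intake_table.csv", "estimate-impact")
      mortality <- read_stage_csv(out_dir, "mortality.csv", "estimate-impact")
      params <- load_parameters(parameter_file)
      for (sc in scenario_labels) {
        shifts <- scenario_shift_table(tab, sc)
        res <- monte_carlo_ui(mortality, shifts, params,
          iterations = iterations, seed = config$seed + 10L
        )
        results[[toupper(sc)]] <- res
        summ <- res$point$summary
        summ$ui_lo <- res$ui$lo[match(summ$group, res$ui$group)]
        summ$ui_hi <- res$ui$hi[match(summ$group, res$ui$group)]
        write_stage_csv(summ, out_dir, paste0("impact_", sc, ".csv"))
      }
      message(
        "estimate-impact: ", length(scenario_labels), " scenarios x ",
        nrow(mortality), " mortality cells, ", iterations, " iterations"
      )
    })
  }

  summary_tab <- NULL
  if ("report" %in% stages) {
    run_stage("report", {
      if (length(results)) {
        summary_tab <- render_summary(results)
      } else {
        # partial rerun: rebuild the summary from the impact CSVs
        rows <- lapply(scenario_labels, function(sc) {
          summ <- read_stage_csv(out_dir, paste0("impact_", sc, ".csv"), "report")
          ref <- summ$deaths[summ$level == "total"]
          keep <- summ[summ$level %in% c("sex", "total"), ]
          tibble::tibble(
            scenario = toupper(sc), sex = keep$group,
            deaths_averted = keep$deaths_averted,
            ui_lo = keep$ui_lo, ui_hi = keep$ui_hi,
            pct_of_reference = round_half_up(100 * keep$deaths_averted / ref, 1)
          )
        })
        summary_tab <- dplyr::bind_rows(rows)
        summary_tab$sex <- factor(summary_tab$sex, levels = c("male", "female", "total"))
        summary_tab <- dplyr::arrange(summary_tab, .data$scenario, .data$sex)
      }
      write_stage_csv(summary_tab, out_dir, "summary.csv")
    })
  }

  manifest <- list(
    tool = paste0("sodiumcra ", as.character(utils::packageVersion("sodiumcra"))),
    seed = config$seed,
    iterations = iterations,
    parameter_file = normalizePath(parameter_file),
    parameter_file_md5 = unname(tools::md5sum(parameter_file)),
    stages = stages,
    input_md5 = as.list(tools::md5sum(
      file.path(out_dir, intersect(
        c("products.csv", "targets.csv", "recall_items.csv", "respondents.csv", "mortality.csv"),
        list.files(out_dir)
      ))
    )),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  names(manifest$input_md5) <- basename(names(manifest$input_md5))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)

  invisible(list(
    results = results,
    summary = summary_tab,
    manifest = manifest_path
  ))
}
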