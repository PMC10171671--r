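#' Load a dose-response parameter set
#'
#' Reads the versioned parameter file (YAML, or the CSV mirror pair) that
#' carries the two epidemiological links of the salt pathway:
#'
#' * `beta` — the salt -> systolic blood pressure dose-response: one linear
#'   slope per adult age range, in mmHg SBP per g/day of salt, with a
#'   standard error;
#' * `rr20` — the SBP -> cause-specific CVD mortality link: one relative risk
#'   per 20 mmHg higher usual SBP for each (ICD-10 cause group, age range),
#'   with a 95% CI.
#'
#' Every entry carries a provenance string naming its source meta-analysis.
#' Validation refuses silently-missing coverage: each of the seven CVD cause
#' groups must have at least one `rr20` entry, slopes must be non-negative,
#' and relative risks must be >= 1.
#'
#' @param path Path to a parameter YAML file. Defaults to the parameter file
#'   bundled with the package.
#' @return An object of class `rr_parameter_set`: a list with tibbles `beta`
#'   (`age_range`, `slope`, `se`, `provenance`) and `rr20` (`cause`,
#'   `age_range`, `rr`, `ci_lower`, `ci_upper`, `log_se`, `provenance`), plus
#'   `version`.
#' @export
load_parameters <- function(path = default_parameter_file()) {
  if (!file.exists(path)) {
    stop("Parameter file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || (is.null(raw$beta) && is.null(raw$rr20))) {
    stop("Parameter file contains no parameters (need `beta` and `rr20` sections): ",
      path,
      call. = FALSE
    )
  }
  if (is.null(raw$beta) || !length(raw$beta)) {
    stop("Parameter file has no `beta` section: ", path, call. = FALSE)
  }
  if (is.null(raw$rr20) || !length(raw$rr20)) {
    stop("Parameter file has no `rr20` section: ", path, call. = FALSE)
  }

  beta <- dplyr::bind_rows(lapply(raw$beta, function(e) {
    tibble::tibble(
      age_range = as.character(e$age_range),
      slope = as.numeric(e$slope_mmhg_per_g_salt),
      se = as.numeric(e$se),
      provenance = as.character(e$provenance %||% NA_character_)
    )
  }))
  rr20 <- dplyr::bind_rows(lapply(raw$rr20, function(e) {
    tibble::tibble(
      cause = as.character(e$cause),
      age_range = as.character(e$age_range),
      rr = as.numeric(e$rr),
      ci_lower = as.numeric(e$ci_lower %||% NA_real_),
      ci_upper = as.numeric(e$ci_upper %||% NA_real_),
      provenance = as.character(e$provenance %||% NA_character_)
    )
  }))
  rr20$log_se <- ifelse(
    is.na(rr20$ci_lower) | is.na(rr20$ci_upper),
    0,
    (log(rr20$ci_upper) - log(rr20$ci_lower)) / (2 * stats::qnorm(0.975))
  )

  set <- structure(
    list(
      version = raw$version %||% 1L,
      beta = beta,
      rr20 = rr20
    ),
    class = "rr_parameter_set"
  )
  validate_parameters(set)
  set
}

#' @rdname load_parameters
#' @export
default_parameter_file <- function() {
  system.file("extdata", "default_parameters.yaml",
    package = "sodiumcra", mustWork = TRUE
  )
}

#' Write a parameter set back to YAML
#'
#' Round-trips through [load_parameters()]: writing a set and reading it back
#' reproduces an identical set.
#'
#' @param params An `rr_parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  out <- list(
    version = params$version,
    beta = lapply(seq_len(nrow(params$beta)), function(i) {
      row <- params$beta[i, ]
      list(
        age_range = row$age_range,
        slope_mmhg_per_g_salt = row$slope,
        se = row$se,
        provenance = row$provenance
      )
    }),
    rr20 = lapply(seq_len(nrow(params$rr20)), function(i) {
      row <- params$rr20[i, ]
      list(
        cause = row$cause,
        age_range = row$age_range,
        rr = row$rr,
        ci_lower = row$ci_lower,
        ci_upper = row$ci_upper,
        provenance = row$provenance
      )
    })
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

validate_parameters <- function(params) {
  stopifnot(inherits(params, "rr_parameter_set"))
  beta <- params$beta
  rr20 <- params$rr20
  if (any(beta$slope < 0)) {
    stop("beta slopes must be non-negative", call. = FALSE)
  }
  if (any(rr20$rr < 1)) {
    bad <- rr20[rr20$rr < 1, ]
    stop(
      "rr20 must be >= 1 for CVD causes; offending entries: ",
      paste(paste0(bad$cause, "@", bad$age_range), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(beta$age_range)) {
    stop("duplicate beta age ranges", call. = FALSE)
  }
  if (anyDuplicated(paste(rr20$cause, rr20$age_range))) {
    stop("duplicate rr20 (cause, age_range) entries", call. = FALSE)
  }
  missing_causes <- setdiff(cvd_causes()$cause, unique(rr20$cause))
  if (length(missing_causes)) {
    stop(
      "rr20 coverage missing for cause group(s): ",
      paste(missing_causes, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(params)
}

#' Resolve dose-response parameters for ages and causes
#'
#' `resolve_beta()` returns the SBP slope applying at each age (the entry
#' whose range contains the age, nearest range as fallback); `resolve_rr20()`
#' does the same for the per-cause RR entries.
#'
#' @param params An `rr_parameter_set`.
#' @param age Numeric vector of ages (typically band midpoints).
#' @param cause Character vector of ICD-10 cause-group codes (recycled
#'   against `age`).
#' @return For `resolve_beta()`, a tibble with `age_range`, `slope`, `se`;
#'   for `resolve_rr20()`, a tibble with `cause`, `age_range`, `rr`, `log_se`.
#' @export
resolve_beta <- function(params, age) {
  ranges <- match_age_range(age, params$beta$age_range)
  idx <- match(ranges, params$beta$age_range)
  tibble::tibble(
    age_range = ranges,
    slope = params$beta$slope[idx],
    se = params$beta$se[idx]
  )
}

#' @rdname resolve_beta
#' @export
resolve_rr20 <- function(params, cause, age) {
  n <- max(length(cause), length(age))
  cause <- rep_len(cause, n)
  age <- rep_len(age, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    entries <- params$rr20[params$rr20$cause == cause[i], ]
    if (!nrow(entries)) {
      stop("No rr20 entries for cause ", cause[i], call. = FALSE)
    }
    rng <- match_age_range(age[i], entries$age_range)
    row <- entries[entries$age_range == rng, ]
    out[[i]] <- tibble::tibble(
      cause = cause[i],
      age_range = rng,
      rr = row$rr,
      log_se = row$log_se
    )
  }
  dplyr::bind_rows(out)
}

#' @export
print.rr_parameter_set <- function(x, ...) {
  cat(
    "<rr_parameter_set> version", x$version, "-",
    nrow(x$beta), "SBP slope entries,",
    nrow(x$rr20), "RR-per-20-mmHg entries across",
    length(unique(x$rr20$cause)), "cause groups\n"
  )
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
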