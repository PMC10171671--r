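#' Adult DRI age/sex strata
#'
#' The analysis stratifies adults into the four Dietary Reference Intake (DRI)
#' age groups, crossed with sex. These labels are used consistently across the
#' intake tables, the scenario builders and the risk-assessment engine.
#'
#' @return Character vector of the four DRI age-group labels.
#' @export
dri_age_groups <- function() {
  c("19-30", "31-50", "51-70", "71+")
}

#' @rdname dri_age_groups
#' @return `stratum_table()` returns a tibble with one row per sex x DRI
#'   age-group cell (`sex`, `age_group`).
#' @export
stratum_table <- function() {
  tidyr::expand_grid(
    sex = c("male", "female"),
    age_group = dri_age_groups()
  )
}

#' Five-year mortality age bands
#'
#' Mortality inputs are stratified by sex and five-year age band from 20-24 up
#' to the open-ended 85+ band, matching national vital-statistics extracts.
#'
#' @return Character vector of band labels, ordered by age.
#' @export
mortality_age_bands <- function() {
  c(paste(seq(20, 80, by = 5), seq(24, 84, by = 5), sep = "-"), "85+")
}

#' The seven ICD-10 cardiovascular cause groups
#'
#' @return Tibble with columns `cause` (ICD-10 range code) and `cause_name`.
#' @export
cvd_causes <- function() {
  tibble::tibble(
    cause = c("I20-25", "I60-69", "I50", "I71", "I26", "I05-09", "I10-15"),
    cause_name = c(
      "Ischaemic heart diseases", "Cerebrovascular diseases", "Heart failure",
      "Aortic aneurysm", "Pulmonary embolism", "Rheumatic heart disease",
      "Hypertensive disease"
    )
  )
}

# Parse an age-range label ("19-30", "85+", "80+") into c(lo, hi); hi is Inf
# for open-ended ranges.
parse_age_range <- function(label) {
  label <- trimws(label)
  if (grepl("\\+$", label)) {
    lo <- as.numeric(sub("\\+$", "", label))
    c(lo, Inf)
  } else {
    parts <- as.numeric(strsplit(label, "-", fixed = TRUE)[[1]])
    if (length(parts) != 2 || anyNA(parts)) {
      stop("Cannot parse age range label: ", label, call. = FALSE)
    }
    parts
  }
}

#' Midpoint of an age band
#'
#' Open-ended bands ("85+") use the band start plus 2.5 years, the same offset
#' as a closed five-year band, so the crosswalk treats them consistently.
#'
#' @param band Character vector of band labels.
#' @return Numeric vector of midpoints in years.
#' @export
age_band_midpoint <- function(band) {
  vapply(band, function(b) {
    r <- parse_age_range(b)
    if (is.finite(r[2])) mean(r) else r[1] + 2.5
  }, numeric(1), USE.NAMES = FALSE)
}

# Map numeric ages onto the labelled range containing them; ages outside all
# ranges fall back to the nearest range. `ranges` is a character vector.
match_age_range <- function(age, ranges) {
  bounds <- t(vapply(ranges, parse_age_range, numeric(2)))
  vapply(age, function(a) {
    hit <- which(a >= bounds[, 1] & a <= bounds[, 2])
    if (length(hit) >= 1) {
      return(ranges[hit[1]])
    }
    # nearest-range fallback by distance to the closed interval
    d <- pmax(bounds[, 1] - a, a - pmin(bounds[, 2], 200), 0)
    ranges[which.min(d)]
  }, character(1))
}

#' Map five-year mortality bands to DRI intake age groups
#'
#' A mortality band is assigned to the DRI group containing its midpoint
#' (e.g. 30-34, midpoint 32, maps to 31-50). Bands younger than all DRI
#' groups fall back to the nearest group.
#'
#' @param band Character vector of five-year band labels.
#' @return Character vector of DRI age-group labels.
#' @export
band_to_dri_group <- function(band) {
  match_age_range(age_band_midpoint(band), dri_age_groups())
}

assert_sex <- function(sex) {
  bad <- setdiff(unique(sex), c("male", "female"))
  if (length(bad)) {
    stop("Unknown sex value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(sex)
}
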