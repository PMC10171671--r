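#' Cap product sodium densities at category benchmark targets
#'
#' The reformulation scenario assumes every branded product whose reported
#' sodium density exceeds its category's benchmark target is reformulated
#' down to exactly the target. Products in a category without a published
#' target, or with no category at all, pass through unchanged.
#'
#' @param products Tibble/data frame with columns `product_id`, `category_id`
#'   (may be `NA` for uncategorized products) and `sodium_mg_per_100g`.
#' @param targets Tibble/data frame with columns `category_id` and
#'   `target_mg_per_100g`; one target per category.
#' @return The product table with `sodium_mg_per_100g` capped and a logical
#'   `capped` column flagging products that were reformulated.
#' @examples
#' products <- tibble::tibble(
#'   product_id = 1:2, category_id = "soup",
#'   sodium_mg_per_100g = c(900, 400)
#' )
#' targets <- tibble::tibble(category_id = "soup", target_mg_per_100g = 600)
#' cap_to_targets(products, targets)
#' @export
cap_to_targets <- function(products, targets) {
  check_columns(products, c("product_id", "category_id", "sodium_mg_per_100g"),
    what = "products"
  )
  check_columns(targets, c("category_id", "target_mg_per_100g"),
    what = "targets"
  )
  if (anyDuplicated(targets$category_id)) {
    dup <- unique(targets$category_id[duplicated(targets$category_id)])
    stop("Duplicate target for category: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(products$sodium_mg_per_100g < 0, na.rm = TRUE)) {
    stop("Negative sodium density in product table", call. = FALSE)
  }
  if (any(targets$target_mg_per_100g <= 0)) {
    stop("Targets must be positive", call. = FALSE)
  }

  out <- dplyr::left_join(
    tibble::as_tibble(products),
    tibble::as_tibble(targets),
    by = "category_id"
  )
  out$capped <- !is.na(out$target_mg_per_100g) &
    out$sodium_mg_per_100g > out$target_mg_per_100g
  out$sodium_mg_per_100g <- ifelse(
    out$capped, out$target_mg_per_100g, out$sodium_mg_per_100g
  )
  out$target_mg_per_100g <- NULL
  out
}

#' Rebuild aggregate food profiles from a (possibly reformulated) supply
#'
#' Recall food codes are linked to branded products through a match map;
#' a matched profile's sodium density is the arithmetic (unweighted) mean of
#' its matched products. Profiles without matched products (unpackaged foods,
#' or foods with no market equivalent) keep the generic density from the
#' reference food file.
#'
#' @param products Product table (`product_id`, `sodium_mg_per_100g`).
#' @param match_map Tibble with columns `profile_id`, `product_id` linking
#'   recall food profiles to branded products.
#' @param generic Tibble with columns `profile_id`, `sodium_mg_per_100g`
#'   giving the generic density of every profile.
#' @return Profile table with columns `profile_id`, `sodium_mg_per_100g` and
#'   `source` (`"matched_aggregate"` or `"unmatched_generic"`).
#' @export
aggregate_profiles <- function(products, match_map, generic) {
  check_columns(products, c("product_id", "sodium_mg_per_100g"), "products")
  check_columns(match_map, c("profile_id", "product_id"), "match_map")
  check_columns(generic, c("profile_id", "sodium_mg_per_100g"), "generic")
  unknown <- setdiff(match_map$product_id, products$product_id)
  if (length(unknown)) {
    stop("match_map references unknown product(s): ",
      paste(utils::head(unknown, 5), collapse = ", "),
      call. = FALSE
    )
  }

  matched <- dplyr::left_join(
    tibble::as_tibble(match_map),
    tibble::as_tibble(products)[, c("product_id", "sodium_mg_per_100g")],
    by = "product_id"
  )
  matched <- dplyr::summarise(
    dplyr::group_by(matched, .data$profile_id),
    sodium_mg_per_100g = mean(.data$sodium_mg_per_100g),
    .groups = "drop"
  )

  out <- tibble::as_tibble(generic)[, c("profile_id", "sodium_mg_per_100g")]
  idx <- match(out$profile_id, matched$profile_id)
  has_match <- !is.na(idx)
  out$sodium_mg_per_100g[has_match] <- matched$sodium_mg_per_100g[idx[has_match]]
  out$source <- ifelse(has_match, "matched_aggregate", "unmatched_generic")

  orphan <- !has_match & is.na(out$sodium_mg_per_100g)
  if (any(orphan)) {
    stop("Profile(s) with no matched products and no generic density: ",
      paste(utils::head(out$profile_id[orphan], 5), collapse = ", "),
      call. = FALSE
    )
  }
  # matched profiles absent from the generic file are appended
  extra <- setdiff(matched$profile_id, out$profile_id)
  if (length(extra)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      profile_id = extra,
      sodium_mg_per_100g = matched$sodium_mg_per_100g[match(extra, matched$profile_id)],
      source = "matched_aggregate"
    ))
  }
  out
}

#' Per respondent-day sodium intake from 24-h recall items
#'
#' Standard recall arithmetic: each reported item contributes
#' `amount_g x density / 100` mg of sodium; items are summed within each
#' (respondent, recall day).
#'
#' @param items Tibble with columns `respondent_id`, `day_index`,
#'   `profile_id`, `amount_g`.
#' @param profiles Profile table with `profile_id`, `sodium_mg_per_100g`.
#' @return Tibble with `respondent_id`, `day_index`, `sodium_mg` (one row per
#'   respondent-day present in `items`).
#' @export
daily_sodium <- function(items, profiles) {
  check_columns(items, c("respondent_id", "day_index", "profile_id", "amount_g"),
    what = "items"
  )
  check_columns(profiles, c("profile_id", "sodium_mg_per_100g"), "profiles")
  idx <- match(items$profile_id, profiles$profile_id)
  if (anyNA(idx)) {
    missing <- unique(items$profile_id[is.na(idx)])
    stop("Recall item(s) reference unknown profile(s): ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  items <- tibble::as_tibble(items)
  items$sodium_mg <- items$amount_g * profiles$sodium_mg_per_100g[idx] / 100
  dplyr::summarise(
    dplyr::group_by(items, .data$respondent_id, .data$day_index),
    sodium_mg = sum(.data$sodium_mg),
    .groups = "drop"
  )
}

#' Survey-weighted DRI cut-point statistics
#'
#' For each stratum, the proportion of the (weighted) population with usual
#' sodium intake at or below the Adequate Intake and the proportion strictly
#' above the Chronic Disease Risk Reduction level. Intake at the AI counts as
#' below/at; the CDRR comparison is strict.
#'
#' @param intakes Tibble with columns `respondent_id`, `usual_mg`, `sex`,
#'   `age_group` and optionally `weight` (defaults to 1).
#' @param ai Adequate Intake cut-point, mg/day (default 1500).
#' @param cdrr Chronic Disease Risk Reduction cut-point, mg/day (default 2300).
#' @return Tibble with per-stratum `n`, `pct_below_ai`, `pct_above_cdrr`
#'   (percent scale).
#' @export
dri_cutpoint_stats <- function(intakes, ai = 1500, cdrr = 2300) {
  check_columns(intakes, c("respondent_id", "usual_mg", "sex", "age_group"),
    what = "intakes"
  )
  intakes <- tibble::as_tibble(intakes)
  if (!nrow(intakes)) stop("Empty intake table", call. = FALSE)
  if (is.null(intakes$weight)) intakes$weight <- 1
  dplyr::summarise(
    dplyr::group_by(intakes, .data$sex, .data$age_group),
    n = dplyr::n(),
    pct_below_ai = 100 * sum(.data$weight * (.data$usual_mg <= ai)) / sum(.data$weight),
    pct_above_cdrr = 100 * sum(.data$weight * (.data$usual_mg > cdrr)) / sum(.data$weight),
    .groups = "drop"
  )
}

check_columns <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(x)
}
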