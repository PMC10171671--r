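test_that("capping reformulates exactly the above-target products", {
  capped <- cap_to_targets(toy_products(), toy_targets())
  # brute-force expectation over rows
  joined <- merge(toy_products(), toy_targets(), all.x = TRUE)
  expected_flag <- !is.na(joined$target_mg_per_100g) &
    joined$sodium_mg_per_100g > joined$target_mg_per_100g
  expect_equal(sum(capped$capped), sum(expected_flag))
  expect_equal(sum(capped$capped), 2) # p1 (900>600) and p3 (700>500)

  expect_equal(capped$sodium_mg_per_100g[capped$product_id == "p1"], 600)
  expect_equal(capped$sodium_mg_per_100g[capped$product_id == "p2"], 400)
  # uncategorized product untouched
  expect_equal(capped$sodium_mg_per_100g[capped$product_id == "p5"], 1200)
  expect_false(capped$capped[capped$product_id == "p5"])
})

test_that("capping is idempotent, never increases density, and errors on duplicate targets", {
  set.seed(7)
  products <- tibble::tibble(
    product_id = seq_len(200),
    category_id = sample(c(letters[1:6], NA), 200, replace = TRUE),
    sodium_mg_per_100g = runif(200, 0, 1500)
  )
  targets <- tibble::tibble(
    category_id = letters[1:5], # category f has no target
    target_mg_per_100g = runif(5, 300, 900)
  )
  once <- cap_to_targets(products, targets)
  twice <- cap_to_targets(once[names(products)], targets)
  expect_equal(twice$sodium_mg_per_100g, once$sodium_mg_per_100g)
  expect_false(any(twice$capped))
  expect_true(all(once$sodium_mg_per_100g <= products$sodium_mg_per_100g))

  dup <- rbind(targets, targets[1, ])
  expect_error(cap_to_targets(products, dup), "Duplicate target")
})

test_that("profile aggregation means matched products and keeps generic values", {
  profiles <- aggregate_profiles(toy_products(), toy_match_map(), toy_profiles())
  expect_equal(
    profiles$sodium_mg_per_100g[profiles$profile_id == "soup_mix"],
    mean(c(900, 400))
  )
  expect_equal(
    profiles$source[profiles$profile_id == "soup_mix"], "matched_aggregate"
  )
  expect_equal(profiles$sodium_mg_per_100g[profiles$profile_id == "fruit"], 5)
  expect_equal(profiles$source[profiles$profile_id == "fruit"], "unmatched_generic")

  # only profiles touched by capping change between baseline and scenario
  capped <- cap_to_targets(toy_products(), toy_targets())
  after <- aggregate_profiles(capped, toy_match_map(), toy_profiles())
  delta <- after$sodium_mg_per_100g - profiles$sodium_mg_per_100g
  expect_true(all(delta[after$profile_id %in% c("soup_mix", "loaf")] < 0))
  expect_equal(delta[after$profile_id == "fruit"], 0)

  # orphan profile: no match, no generic value
  orphan <- tibble::tibble(profile_id = "ghost", sodium_mg_per_100g = NA_real_)
  expect_error(
    aggregate_profiles(toy_products(), toy_match_map(), rbind(toy_profiles(), orphan)),
    "no matched products and no generic"
  )
  # match map referencing a non-existent product
  bad_map <- rbind(toy_match_map(), tibble::tibble(profile_id = "x", product_id = "p99"))
  expect_error(aggregate_profiles(toy_products(), bad_map, toy_profiles()), "unknown product")
})

test_that("daily sodium is exact recall arithmetic and additive over partitions", {
  profiles <- tibble::tibble(
    profile_id = c("a", "b"),
    sodium_mg_per_100g = c(500, 200)
  )
  items <- tibble::tibble(
    respondent_id = "r1", day_index = 1L,
    profile_id = c("a", "b"), amount_g = c(100, 50)
  )
  expect_equal(daily_sodium(items, profiles)$sodium_mg, 100 * 5 + 50 * 2) # 600

  # row-by-row brute-force oracle on a random 10-respondent fixture
  set.seed(11)
  fix <- tibble::tibble(
    respondent_id = sample(paste0("r", 1:10), 60, replace = TRUE),
    day_index = sample(1:2, 60, replace = TRUE),
    profile_id = sample(c("a", "b"), 60, replace = TRUE),
    amount_g = runif(60, 5, 300)
  )
  got <- daily_sodium(fix, profiles)
  dens <- c(a = 500, b = 200)
  fix$mg <- fix$amount_g * dens[fix$profile_id] / 100
  oracle <- aggregate(mg ~ respondent_id + day_index, fix, sum)
  merged <- merge(got, oracle)
  expect_equal(merged$sodium_mg, merged$mg)

  # additivity over an arbitrary item partition
  half <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  part1 <- daily_sodium(fix[half, 1:4], profiles)
  part2 <- daily_sodium(fix[!half, 1:4], profiles)
  total <- merge(part1, part2, by = c("respondent_id", "day_index"), all = TRUE)
  total$sum <- rowSums(total[, c("sodium_mg.x", "sodium_mg.y")], na.rm = TRUE)
  merged2 <- merge(got, total)
  expect_equal(merged2$sodium_mg, merged2$sum)

  expect_error(
    daily_sodium(tibble::tibble(
      respondent_id = "r", day_index = 1L, profile_id = "zzz", amount_g = 1
    ), profiles),
    "unknown profile"
  )
})

test_that("DRI cut-point proportions are weighted, with AI <= and CDRR >", {
  base <- tibble::tibble(
    respondent_id = paste0("r", 1:2), sex = "male", age_group = "31-50",
    usual_mg = c(1400, 2400), weight = 1
  )
  got <- dri_cutpoint_stats(base)
  expect_equal(got$pct_below_ai, 50)
  expect_equal(got$pct_above_cdrr, 50)

  # all below AI
  low <- dplyr::mutate(base, usual_mg = 1400)
  expect_equal(dri_cutpoint_stats(low)$pct_below_ai, 100)
  expect_equal(dri_cutpoint_stats(low)$pct_above_cdrr, 0)

  # boundary semantics: at the AI counts below/at, at the CDRR does not count above
  at_bounds <- dplyr::mutate(base, usual_mg = c(1500, 2300))
  expect_equal(dri_cutpoint_stats(at_bounds)$pct_below_ai, 50)
  expect_equal(dri_cutpoint_stats(at_bounds)$pct_above_cdrr, 0)

  # weighted toy set against enumerated brute force
  wtd <- tibble::tibble(
    respondent_id = paste0("r", 1:3), sex = "female", age_group = "51-70",
    usual_mg = c(1200, 2000, 2500), weight = c(1, 2, 3)
  )
  got <- dri_cutpoint_stats(wtd)
  expect_equal(got$pct_below_ai, 100 * 1 / 6)
  expect_equal(got$pct_above_cdrr, 100 * 3 / 6)

  expect_error(dri_cutpoint_stats(wtd[0, ]), "Empty")
})
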