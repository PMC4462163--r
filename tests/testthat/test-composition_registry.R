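test_that("recipe-based whole-grain derivation applies water and processing losses", {
  water <- grain_water_content()
  wheat_w <- water$water_percent[water$grain == "wheat"]
  oat_w <- water$water_percent[water$grain == "oats"]

  # 70 g wholemeal flour per 100 g bread at 14 % water -> 60.2 g DM wheat
  out <- derive_wg_percent(data.frame(
    grain = "wheat", fresh_mass_per_100g_food = 70, water_percent = wheat_w))
  expect_equal(out, c(wheat = 70 * (1 - wheat_w / 100)))
  expect_equal(unname(out), 60.2)

  # 50 g whole oat at 8.9 % water -> 45.55 g DM oats
  out <- derive_wg_percent(data.frame(
    grain = "oats", fresh_mass_per_100g_food = 50, water_percent = oat_w))
  expect_equal(unname(out), 45.55)

  # empty recipe is a zero-whole-grain food
  expect_length(derive_wg_percent(data.frame()), 0)

  # same grain from two ingredients accumulates; processing loss multiplies
  out <- derive_wg_percent(data.frame(
    grain = c("wheat", "wheat"),
    fresh_mass_per_100g_food = c(40, 20),
    water_percent = c(14, 14),
    processing_loss_percent = c(0, 10)))
  expect_equal(unname(out), 40 * 0.86 + 20 * 0.86 * 0.9)
})

test_that("derivation rejects out-of-range fields by name and impossible totals", {
  expect_error(derive_wg_percent(data.frame(
    grain = "spelt", fresh_mass_per_100g_food = 10, water_percent = 10)),
    "unknown grain")
  expect_error(derive_wg_percent(data.frame(
    grain = "wheat", fresh_mass_per_100g_food = 120, water_percent = 10)),
    "fresh_mass_per_100g_food")
  expect_error(derive_wg_percent(data.frame(
    grain = "wheat", fresh_mass_per_100g_food = 10, water_percent = 100)),
    "water_percent")
  expect_error(derive_wg_percent(data.frame(
    grain = "wheat", fresh_mass_per_100g_food = 10, water_percent = 10,
    processing_loss_percent = -1)), "processing_loss_percent")
})

test_that("derivation is monotone in fresh mass and in the loss percents", {
  set.seed(42)
  for (i in 1:20) {
    m <- runif(1, 5, 80); w <- runif(1, 0, 40); l <- runif(1, 0, 40)
    base <- unname(derive_wg_percent(data.frame(
      grain = "rye", fresh_mass_per_100g_food = m, water_percent = w,
      processing_loss_percent = l)))
    up_m <- unname(derive_wg_percent(data.frame(
      grain = "rye", fresh_mass_per_100g_food = m + 5, water_percent = w,
      processing_loss_percent = l)))
    up_w <- unname(derive_wg_percent(data.frame(
      grain = "rye", fresh_mass_per_100g_food = m, water_percent = w + 5,
      processing_loss_percent = l)))
    expect_gt(up_m, base)
    expect_lt(up_w, base)
  }
})

test_that("cooked-equivalent mass undoes cooking loss", {
  expect_equal(cooked_equivalent_mass(85.4, 14.6), 100)
  expect_equal(cooked_equivalent_mass(123.4, 0), 123.4)
  expect_equal(cooked_equivalent_mass(0, 50), 0)
  expect_error(cooked_equivalent_mass(10, 100), "cooking_loss_percent")
  expect_error(cooked_equivalent_mass(-1, 10), "consumed_g")

  # cooking then mapping back is the identity for any loss in [0, 100)
  set.seed(7)
  m <- runif(25, 0, 500); l <- runif(25, 0, 99.9)
  expect_equal(cooked_equivalent_mass(m * (1 - l / 100), l), m)
})

test_that("registry round-trips losslessly through CSV and TSV", {
  reg <- fixture_registry()
  p <- tempfile(fileext = ".csv")
  save_registry(reg, p)
  back <- load_registry(p)
  expect_equal(as.data.frame(back), as.data.frame(reg))

  # tab-delimited input is auto-detected
  pt <- tempfile(fileext = ".tsv")
  write.table(as.data.frame(reg), pt, sep = "\t", row.names = FALSE, na = "")
  expect_equal(as.data.frame(load_registry(pt)), as.data.frame(reg))
})

test_that("registry validation rejects bad records with row numbers", {
  base <- as.data.frame(fixture_registry())

  dup <- rbind(base, base[1, ])
  err <- tryCatch(as_wg_registry(dup), error = conditionMessage)
  expect_match(err, "duplicate food_code")
  expect_match(err, "1, 6")

  over <- base; over$wheat[1] <- 96; over$oats[1] <- 10
  expect_error(as_wg_registry(over), "exceeds 100")

  badgrp <- base; badgrp$food_group[2] <- "beverages"
  expect_error(as_wg_registry(badgrp), "unknown food_group 'beverages'")

  badloss <- base; badloss$cooking_loss_percent[2] <- 100
  expect_error(as_wg_registry(badloss), "cooking_loss_percent")

  orphan <- base; orphan$cooked_form_of[2] <- "NOPE"
  expect_error(as_wg_registry(orphan), "unknown food_code")

  both <- base; both$wheat[2] <- 10
  expect_error(as_wg_registry(both), "zero own grain content")

  extra <- base; extra$spelt <- 1
  expect_error(as_wg_registry(extra), "unknown registry column")
})

test_that("every record keeps total content within [0, 100] and cooked foods inherit the parent percent", {
  reg <- default_registry()
  tot <- rowSums(as.matrix(as.data.frame(reg)[grain_types()]))
  expect_true(all(tot >= 0 & tot <= 100))

  pct <- food_wg_percent(reg)
  expect_equal(unname(pct["WB002"]), 51 / (1 - 14.6 / 100))
  expect_equal(unname(pct["WB001"]), 51)
})
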