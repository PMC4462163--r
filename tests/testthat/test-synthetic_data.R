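test_that("the generated registry spans all food groups and grain types", {
  reg <- synthetic_registry()
  expect_setequal(unique(reg$food_group), food_groups())
  gm <- as.matrix(as.data.frame(reg)[grain_types()])
  expect_true(all(colSums(gm) > 0))
  # contents straddle the cut-off tiers
  pct <- food_wg_percent(reg)
  expect_true(any(pct < 10) && any(pct >= 10 & pct < 51) && any(pct >= 51))
})

test_that("generation is deterministic under a fixed seed and streams are per participant", {
  cfg <- synthetic_config(n_participants = 60, seed = 123)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(synthetic_config(n_participants = 60, seed = 124))
  expect_false(identical(d1$diary, d3$diary))

  # the first participants are unchanged when the population grows
  big <- generate_dataset(synthetic_config(n_participants = 80, seed = 123))
  expect_identical(big$participants[1:60, ], d1$participants)
})

test_that("non-consumer probability 1 produces only zero intakes", {
  cfg <- synthetic_config(n_participants = 40, seed = 5,
                          nonconsumer_prob = c(adult = 1, child = 1))
  ds <- generate_dataset(cfg)
  expect_true(all(ds$ground_truth$gt_gd_any == 0))
  # the diary still records the non-whole-grain filler foods
  expect_true(all(ds$diary$food_code == "NWG01"))
})

test_that("participant tables respect the survey contracts", {
  ds <- generate_dataset(synthetic_config(n_participants = 300, seed = 8))
  expect_silent(as_participants(ds$participants))
  expect_true(all(ds$participants$n_diary_days %in% c(3, 4)))
  expect_true(all(ds$diary$food_code %in% c(ds$registry$food_code, "NWG01")))
  # some NS-SEC missingness, both sexes, children and adults present
  expect_gt(sum(is.na(ds$participants$nssec)), 0)
  expect_setequal(unique(ds$participants$sex), c("male", "female"))
  expect_true(any(ds$participants$age_years < 18) &&
                any(ds$participants$age_years >= 18))
})

test_that("the pipeline recovers the generator's ground-truth intakes exactly", {
  ds <- generate_dataset(synthetic_config(n_participants = 200, seed = 77))
  est <- estimate_all(ds$diary, ds$participants, ds$registry)
  expect_equal(est$wg_gd_any, ds$ground_truth$gt_gd_any)
  expect_equal(est$wg_gd_ge10, ds$ground_truth$gt_gd_ge10)
  expect_equal(est$wg_gd_ge51, ds$ground_truth$gt_gd_ge51)
  # and all tier invariants hold on generated data
  expect_true(all(est$wg_gd_any >= est$wg_gd_ge10 &
                    est$wg_gd_ge10 >= est$wg_gd_ge51 &
                    est$wg_gd_ge51 >= 0))
})

test_that("observed non-consumer fractions are binomial around the configured rate", {
  cfg <- synthetic_config(n_participants = 2000, seed = 99)
  ds <- generate_dataset(cfg)
  adult <- ds$participants$age_years >= 18
  n_a <- sum(adult)
  k <- sum(ds$ground_truth$gt_gd_any[adult] == 0)
  ci <- qbinom(c(0.005, 0.995), n_a, 0.18)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("calibration hits target medians and responds monotonically", {
  base <- synthetic_config(n_participants = 1200, seed = 42)
  cfg <- calibrate_config(base, targets = list(median_adult = 20,
                                               median_child = 13),
                          tol = 0.1)
  got <- attr(cfg, "achieved")
  expect_lt(abs(got[["adult"]] - 20), 2)
  expect_lt(abs(got[["child"]] - 13), 1.3)

  # doubling the target roughly doubles the generated median
  cfg2 <- calibrate_config(base, targets = list(median_adult = 40), tol = 0.1)
  expect_gt(attr(cfg2, "achieved")[["adult"]] / got[["adult"]], 1.6)
  expect_lt(attr(cfg2, "achieved")[["adult"]] / got[["adult"]], 2.4)

  # a zero non-consumer target makes everyone a consumer
  cfg0 <- calibrate_config(base, targets = list(nonconsumer_adult = 0,
                                                nonconsumer_child = 0))
  ds0 <- generate_dataset(cfg0)
  expect_true(all(ds0$ground_truth$gt_gd_any > 0))

  expect_error(calibrate_config(base, targets = list(median_adult = -5)),
               "positive")
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(nonconsumer_prob = c(adult = 1.2, child = 0)),
               "probabilities")
  expect_error(synthetic_config(portion_sdlog = 0), "sd")
  expect_error(synthetic_config(diary_day_probs = c("4" = 0.5, "3" = 0.4)),
               "sum to 1")
})

test_that("datasets round-trip through the CSV writers and loaders", {
  ds <- generate_dataset(synthetic_config(n_participants = 30, seed = 3))
  dir <- tempfile()
  write_dataset(ds, dir)
  reg <- load_registry(file.path(dir, "registry.csv"))
  par <- load_participants(file.path(dir, "participants.csv"))
  dia <- load_diary(file.path(dir, "diary.csv"), reg)
  expect_equal(as.data.frame(reg), as.data.frame(ds$registry))
  expect_equal(par$participant_id, ds$participants$participant_id)
  expect_equal(nrow(dia), nrow(ds$diary))
  est <- estimate_all(dia, par, reg)
  expect_equal(est$wg_gd_any, ds$ground_truth$gt_gd_any, tolerance = 1e-12)
})
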