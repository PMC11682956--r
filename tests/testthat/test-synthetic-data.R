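test_that("generated populations match the configured demography", {
  pop <- generate_population(1000, seed = 21)
  expect_equal(mean(pop$sex == "male"), 0.828, tolerance = 0.03 / 0.828)
  expect_true(all(pop$age >= 2 & pop$age <= 11))
  expect_true(all(pop$weight >= 10 & pop$weight <= 60))
  # zero growth spread: weight collapses to the growth-table median
  pop0 <- generate_population(50, weight_cv = 0, seed = 2)
  expect_equal(pop0$weight,
               pmin(pmax(median_weight_for_age(pop0$age, pop0$sex), 10), 60))
  # median weight non-decreasing in age for both sexes
  ages <- 2:12
  expect_true(all(diff(median_weight_for_age(ages, "male")) >= 0))
  expect_true(all(diff(median_weight_for_age(ages, "female")) >= 0))
  expect_error(generate_population(10, age_range = c(5, 5)), "increasing")
})

test_that("weight-band dose lookup uses half-open bands and flags out-of-range", {
  b3 <- weight_bands_phase3()
  expect_equal(assign_weight_band_dose(20.5, b3), 4)
  expect_equal(assign_weight_band_dose(50.0, b3), 14)
  expect_equal(assign_weight_band_dose(13.6, b3), 2) # below 14 stays in 10-13
  expect_equal(assign_weight_band_dose(c(10, 34.9, 35), b3), c(2, 6, 10))
  expect_error(assign_weight_band_dose(9, b3), "outside")
})

test_that("regimens implement titration, half-dose low arm and placebo crossover", {
  design <- phase2_design()
  plc <- build_regimen(list(weight = 25, arm = "placebo"), design)
  expect_true(all(plc$start >= 84))
  expect_true(all(plc$start < 168))
  high <- build_regimen(list(weight = 25, arm = "high"), design)
  expect_equal(unique(high$amount_mg[high$start < 14]), 3500)
  expect_equal(unique(high$amount_mg[high$start >= 14]), 7000)
  expect_equal(nrow(high), 336) # BID over 168 days
  low <- build_regimen(list(weight = 25, arm = "low"), design)
  expect_true(all(low$amount_mg == 3500))
  # low-arm total equals half the high arm's post-titration rate x duration
  expect_equal(sum(low$amount_mg), 0.5 * 7000 * 336)
  expect_error(build_regimen(list(weight = 25, arm = "mystery"), design),
               "unknown arm")
})

test_that("noise-free placebo subject traces the linear progression at the visits", {
  p0 <- model_parameters(ranef = random_effect_spec(0, 0, 0, 0, 0, 0))
  demog <- tibble::tibble(id = 1, age = 5, weight = 20, sex = "male",
                          arm = "placebo")
  ds <- simulate_dataset(phase2_design(), p0, demog = demog, seed = 1)
  expect_equal(ds$observations$score[1:2], c(48.51, 49.77))
  # after the week-12 crossover the placebo arm carries drug effect too
  expect_gt(ds$observations$score[3], 48.51 + 0.015 * 168)
})

test_that("simulated datasets are seed-reproducible with balanced arms", {
  params <- final_params()
  d1 <- simulate_dataset(phase2_design(), params, n = 30, seed = 7)
  d2 <- simulate_dataset(phase2_design(), params, n = 30, seed = 7)
  expect_identical(d1$observations, d2$observations)
  expect_identical(d1$dosing, d2$dosing)
  counts <- table(d1$demographics$arm)
  expect_true(max(counts) - min(counts) <= 1)
  # no dosing at or beyond treatment end, observations only at visit days
  expect_true(all(d1$dosing$start < 168))
  expect_true(all(d1$observations$time %in% c(0, 84, 168, 252)))
})

test_that("placebo-arm mean change at week 12 reflects the progression slope", {
  design <- trial_design(arms = "placebo", arm_ratio = 1)
  ds <- simulate_dataset(design, final_params(), n = 2500, seed = 31)
  d <- delta_score(ds)
  expect_equal(mean(d$delta), 0.015 * 84, tolerance = 0.12 / 1.26)
})

test_that("visit dropout removes post-baseline visits at the configured rate", {
  design <- phase2_design(dropout_prob = 0.3)
  ds <- simulate_dataset(design, final_params(), n = 250, seed = 9)
  obs <- ds$observations
  expect_true(all(!obs$missing[obs$time == 0]))
  post <- obs$missing[obs$time > 0]
  expect_equal(mean(post), 0.3, tolerance = 0.1)
  expect_true(all(is.na(obs$score[obs$missing])))
})
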