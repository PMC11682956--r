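test_that("delta_score differences the right visits and excludes incomplete subjects", {
  obs <- tibble::tibble(id = rep(1:3, each = 2),
                        time = rep(c(0, 84), 3),
                        score = c(50, 50, 48, 51, 47, 49),
                        missing = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  d <- suppressMessages(delta_score(obs))
  expect_equal(d$delta, c(0, 3))
  expect_equal(attr(d, "excluded"), 3)
  # deterministic placebo typical subject gains kprog * 84
  p0 <- model_parameters(ranef = random_effect_spec(0, 0, 0, 0, 0, 0))
  demog <- tibble::tibble(id = 1, age = 5, weight = 20, sex = "male",
                          arm = "placebo")
  ds <- simulate_dataset(phase2_design(), p0, demog = demog, seed = 1)
  expect_equal(delta_score(ds)$delta, 1.26)
})

test_that("target attainment uses a strict threshold", {
  expect_equal(target_attainment(c(3, 3, 3)), 100)
  expect_equal(target_attainment(c(1, 2, 3)), 100 / 3)
  expect_equal(target_attainment(c(1, 2, 2)), 0)
  expect_error(target_attainment(numeric()), "empty")
})

test_that("mg/kg/day ranges match the weight-band arithmetic", {
  expect_equal(unname(mgkg_range(2, 10, 13)), c(308, 400))
  expect_equal(unname(mgkg_range(4, 14, 20)), c(400, 571))
  expect_equal(unname(mgkg_range(1, 1000, 1000)), c(2, 2))
  expect_error(mgkg_range(2, -1, 10), "positive")
})

test_that("dose scenarios keep percentile order, bounded attainment and dose monotonicity", {
  sc <- run_dose_scenarios(weight_bands_phase3(), final_params(),
                           n_per_band = 60, seed = 23)
  expect_equal(nrow(sc), 5)
  expect_true(all(sc$p5 <= sc$p50 & sc$p50 <= sc$p95))
  expect_true(all(sc$attainment >= 0 & sc$attainment <= 100))
  expect_true(all(sc$placebo_p5 <= sc$placebo_p50 &
                    sc$placebo_p50 <= sc$placebo_p95))
  # treated beats placebo in every band; top band beats bottom band
  expect_true(all(sc$attainment > sc$placebo_attainment))
  expect_gt(sc$attainment[sc$dose_g_bid == 14],
            sc$attainment[sc$dose_g_bid == 2])
  expect_equal(sc$mgkg_min[1], 308)
  expect_equal(sc$mgkg_max[1], 400)
})

test_that("median change is monotone in dose for matched subjects and etas", {
  params <- final_params()
  demog <- generate_population(80, seed = 24)
  demog$weight <- pmax(demog$weight, 10)
  med <- vapply(c(2000, 6000, 14000), function(dose) {
    d <- withr::with_seed(25, astpkpd:::.simulate_band_cohort(
      demog, rep(dose, nrow(demog)), params, days = 84))
    median(d)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("a null drug effect makes treated and placebo cohorts indistinguishable", {
  base <- final_params()
  null <- model_parameters(
    pk = base$pk,
    pd = pd_parameters(ke0 = base$pd$ke0, e0 = base$pd$e0,
                       beta_age = base$pd$beta_age, deff = 1e-12,
                       kprog = base$pd$kprog),
    ranef = base$ranef)
  demog <- generate_population(400, seed = 26)
  treated <- withr::with_seed(27, astpkpd:::.simulate_band_cohort(
    demog, rep(4000, 400), null, days = 84))
  placebo <- withr::with_seed(28, astpkpd:::.simulate_band_cohort(
    demog, rep(0, 400), null, days = 84))
  expect_gt(stats::ks.test(treated, placebo)$p.value, 0.01)
})

test_that("parameter uncertainty widens the percentile bands", {
  bands <- weight_bands_phase3()[2, ]
  fixed <- run_dose_scenarios(bands, final_params(), n_per_band = 150,
                              seed = 29)
  unc <- run_dose_scenarios(bands, final_params(), n_per_band = 150,
                            include_uncertainty = TRUE, seed = 29)
  expect_gte(unc$p95 - unc$p5, fixed$p95 - fixed$p5)
})

test_that("fixed-dose and mg/kg regimens coincide at the exact equivalence weight", {
  bands <- tibble::tibble(band = "10-13 kg", lower = 10, upper = 14,
                          dose_g = 2)
  demog <- tibble::tibble(id = 1:20, age = 3, weight = 10, sex = "male")
  cmp <- compare_fixed_vs_mgkg(bands, mgkg_bid = 200,
                               params = final_params(),
                               population = demog, seed = 30)
  expect_equal(cmp$median_diff, 0)
  expect_equal(cmp$median_fixed, cmp$median_mgkg)
})

test_that("paired fixed versus mg/kg differences are small against between-subject spread", {
  cmp <- compare_fixed_vs_mgkg(weight_bands_phase3()[2:3, ], mgkg_bid = 200,
                               params = final_params(), n_per_band = 80,
                               seed = 31)
  expect_true(all(abs(cmp$median_diff) < cmp$iqr_fixed))
})

test_that("forest ratios anchor at the reference bin and follow the power laws", {
  pop <- tibble::tibble(id = 1:40, age = rep(c(3, 11), 20),
                        weight = rep(c(12, 52), 20), sex = "male")
  fr <- forest_ratios(pop, final_params(),
                      weight_breaks = c(10, 14, 60),
                      age_breaks = c(2, 6, 12), include_iiv = FALSE)
  expect_true(all(fr$ratio[fr$reference] == 1))
  cl_w <- fr[fr$quantity == "CL/F" & fr$covariate == "weight", ]
  expect_equal(cl_w$ratio[1], (12 / 52)^0.75, tolerance = 1e-10)
  # beta_age < 0: younger bin has the higher baseline
  e0_a <- fr[fr$quantity == "E0" & fr$covariate == "age", ]
  expect_gt(e0_a$ratio[1], 1)
  expect_equal(e0_a$ratio[1], (3 / 11)^(-0.21), tolerance = 1e-10)
})

test_that("simulation summaries and forest tables plot cleanly", {
  sc <- run_dose_scenarios(weight_bands_phase3()[1:2, ], final_params(),
                           n_per_band = 30, seed = 33)
  expect_s3_class(autoplot(sc), "ggplot")
  pop <- generate_population(150, seed = 34)
  fr <- forest_ratios(pop, final_params(), seed = 35)
  expect_s3_class(autoplot(fr), "ggplot")
  expect_silent(ggplot2::ggplot_build(autoplot(fr)))
})
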