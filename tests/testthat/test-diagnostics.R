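test_that("population prediction at baseline reproduces the typical baseline score", {
  p0 <- model_parameters(ranef = random_effect_spec(0.1, 0.1, 0.5, 0.01,
                                                    0.2, 1))
  demog <- tibble::tibble(id = 1:4, age = 5, weight = 20, sex = "male",
                          arm = "placebo")
  ds <- simulate_dataset(phase2_design(), p0, demog = demog, seed = 2)
  g <- gof_table(ds, p0)
  expect_equal(g$pred[g$time == 0], rep(48.51, 4))
  expect_equal(g$iwres, (g$observed - g$ipred) / 1)
})

test_that("IWRES is flagged undefined at zero sigma and calibrated when well specified", {
  p0 <- model_parameters(ranef = random_effect_spec(0, 0, 0, 0, 0, 0))
  demog <- tibble::tibble(id = 1:3, age = 5, weight = 20, sex = "male",
                          arm = "placebo")
  ds0 <- simulate_dataset(phase2_design(), p0, demog = demog, seed = 2)
  expect_warning(g0 <- gof_table(ds0, p0), "sigma")
  expect_true(all(is.na(g0$iwres)))
  # near-zero IIV and a rich visit schedule: empirical-Bayes shrinkage is
  # negligible, so IWRES should be standard normal
  rich <- trial_design(visit_days = seq(0, 252, by = 21))
  p_small <- model_parameters(
    ranef = random_effect_spec(1e-3, 1e-3, 1e-3, 1e-4, 0, 1.6))
  ds <- simulate_dataset(rich, p_small, n = 160, seed = 15)
  g <- gof_table(ds, p_small)
  expect_equal(mean(g$iwres), 0, tolerance = 0.05)
  expect_equal(sd(g$iwres), 1, tolerance = 0.03)
})

test_that("pc-VPC bins at the nominal visits and degenerates cleanly at one replicate", {
  params <- final_params()
  ds <- simulate_dataset(phase2_design(), params, n = 40, seed = 16)
  vp <- pc_vpc(ds, params, n_sim = 1, seed = 1)
  expect_equal(length(unique(vp$bin)), 4)
  expect_equal(sort(unique(vp$bin_time)), c(0, 84, 168, 252))
  expect_equal(vp$env_lo, vp$simulated)
  expect_equal(vp$env_hi, vp$simulated)
  # percentile ordering within every bin
  vp2 <- pc_vpc(ds, params, n_sim = 30, seed = 2)
  byb <- split(vp2$observed, vp2$bin)
  expect_true(all(vapply(byb, function(x) !is.unsorted(x), logical(1))))
})

test_that("prediction correction is the identity when one population prediction rules a bin", {
  params <- final_params()
  demog <- tibble::tibble(id = 1:30, age = 6, weight = 21, sex = "male",
                          arm = "high")
  ds <- simulate_dataset(phase2_design(), params, demog = demog, seed = 17)
  vp <- pc_vpc(ds, params, n_sim = 5, seed = 3)
  tfac <- factor(ds$observations$time, levels = c(0, 84, 168, 252))
  raw <- vapply(split(ds$observations$score, tfac),
                stats::quantile, numeric(3), probs = c(0.05, 0.5, 0.95))
  expect_equal(vp$observed, as.vector(raw))
})

test_that("self-simulated data stay inside the VPC envelopes most of the time", {
  params <- final_params()
  hits <- 0; total <- 0
  for (s in 1:6) {
    ds <- simulate_dataset(phase2_design(), params, n = 80, seed = 300 + s)
    vp <- pc_vpc(ds, params, n_sim = 200, seed = 400 + s)
    hits <- hits + sum(vp$observed >= vp$env_lo & vp$observed <= vp$env_hi)
    total <- total + nrow(vp)
  }
  expect_gte(hits / total, 0.9)
})

test_that("VPC envelopes widen with the residual SD", {
  base <- final_params()
  lo <- model_parameters(pk = base$pk, pd = base$pd,
                         ranef = random_effect_spec(0.21, 0.2, 1.4, 0.018,
                                                    0.48, 0.8))
  hi <- model_parameters(pk = base$pk, pd = base$pd,
                         ranef = random_effect_spec(0.21, 0.2, 1.4, 0.018,
                                                    0.48, 3.2))
  ds <- simulate_dataset(phase2_design(), base, n = 40, seed = 18)
  w <- function(p) {
    vp <- pc_vpc(ds, p, n_sim = 40, seed = 5)
    mean(vp$env_hi - vp$env_lo)
  }
  expect_gt(w(hi), w(lo))
})

test_that("diagnostic plots build without evaluation errors", {
  params <- final_params()
  ds <- simulate_dataset(phase2_design(), params, n = 20, seed = 19)
  vp <- pc_vpc(ds, params, n_sim = 10, seed = 6)
  pl <- autoplot(vp)
  expect_s3_class(pl, "ggplot")
  expect_silent(ggplot2::ggplot_build(pl))
  g <- gof_table(ds, params)
  expect_s3_class(plot_gof(g), "ggplot")
})
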