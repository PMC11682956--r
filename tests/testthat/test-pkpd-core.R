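test_that("allometric scaling follows the power law and rejects bad input", {
  expect_equal(allometric_scale(100, 70, 0.75, 70), 100)
  expect_equal(allometric_scale(100, 35, 1.0, 70), 50)
  # direct power-law arithmetic, cross-checked in log space
  expect_equal(allometric_scale(504, 20.5, 0.75, 70),
               exp(log(504) + 0.75 * (log(20.5) - log(70))))
  expect_error(allometric_scale(100, -5, 0.75, 70), "positive")
  pk <- scale_pk(pk_parameters(), 20.5)
  expect_equal(pk$cl_f, 504 * (20.5 / 70)^0.75)
  expect_equal(pk$v1_f, 28 * 20.5 / 70)
})

test_that("plasma concentration is zero without dosing and rejects negative time", {
  pk <- pk_parameters()
  expect_equal(plasma_concentration(pk, regimen(), c(0, 1, 10)), c(0, 0, 0))
  expect_error(plasma_concentration(pk, regimen(0, 2000), -1), "non-negative")
})

test_that("closed-form plasma and effect-site match an ODE oracle", {
  withr::with_seed(101, {
    for (draw in 1:5) {
      pk <- pk_parameters(cl_f = runif(1, 100, 900),
                          v1_f = runif(1, 10, 60),
                          q_f = runif(1, 20, 150),
                          v2_f = runif(1, 15, 80),
                          d1 = runif(1, 0.03, 0.12))
      ke0 <- runif(1, 0.004, 0.05)
      reg <- regimen(start = c(0, 0.5, 1, 1.5), amount_mg = 2000,
                     duration = pk$d1)
      times <- seq(0.01, 4, by = 0.01)
      cp <- plasma_concentration(pk, reg, times)
      ce <- effect_site_concentration(ke0, times, pk = pk, reg = reg)
      ode_fn <- function(t, y, p) {
        inflow <- sum(1000 * reg$amount_mg / reg$duration *
                        (t >= reg$start & t < reg$start + reg$duration))
        cpt <- y[1] / p$v1
        list(c(inflow - p$cl * cpt - p$q * cpt + p$q * y[2] / p$v2,
               p$q * cpt - p$q * y[2] / p$v2,
               ke0 * (cpt - y[3])))
      }
      sol <- deSolve::ode(c(0, 0, 0), c(0, times), ode_fn,
                          list(cl = pk$cl_f, v1 = pk$v1_f, q = pk$q_f,
                               v2 = pk$v2_f),
                          rtol = 1e-10, atol = 1e-10)[-1, ]
      expect_lt(max(abs(cp - sol[, 2] / pk$v1_f) / pmax(sol[, 2] / pk$v1_f, 1)),
                1e-6)
      expect_lt(max(abs(ce - sol[, 4]) / pmax(sol[, 4], 1e-3)), 1e-6)
    }
  })
})

test_that("single-dose AUC equals dose over clearance", {
  pk <- scale_pk(pk_parameters(), 20.5)
  reg <- regimen(0, 2000, pk$d1)
  auc <- stats::integrate(function(t) plasma_concentration(pk, reg, t),
                          0, Inf, rel.tol = 1e-9, subdivisions = 2000)$value
  expect_equal(auc, 2000 * 1000 / pk$cl_f, tolerance = 1e-3)
})

test_that("superposition and dose-linearity hold", {
  pk <- scale_pk(pk_parameters(), 25)
  times <- c(0.2, 0.6, 1.3, 2.5, 5)
  single <- lapply(c(0, 0.5, 1), function(s) {
    plasma_concentration(pk, regimen(s, 4000, pk$d1), times)
  })
  combined <- plasma_concentration(pk, regimen(c(0, 0.5, 1), 4000, pk$d1),
                                   times)
  expect_equal(combined, Reduce(`+`, single), tolerance = 1e-9)
  # doubling every dose doubles both concentrations pointwise
  reg1 <- regimen(c(0, 0.5, 1), 4000, pk$d1)
  reg2 <- regimen(c(0, 0.5, 1), 8000, pk$d1)
  expect_equal(2 * plasma_concentration(pk, reg1, times),
               plasma_concentration(pk, reg2, times), tolerance = 1e-12)
  expect_equal(2 * effect_site_concentration(0.0065, times, pk = pk, reg = reg1),
               effect_site_concentration(0.0065, times, pk = pk, reg = reg2),
               tolerance = 1e-12)
})

test_that("effect site lags plasma and rises per the closed form", {
  pk <- scale_pk(pk_parameters(), 25)
  reg <- regimen(seq(0, 13.5, 0.5), 4000, pk$d1)
  times <- seq(0, 40, by = 0.05)
  prof <- concentration_profile(pk, reg, times, ke0 = 0.05)
  expect_lte(max(prof$effect_site), max(prof$plasma))
  expect_gte(times[which.max(prof$effect_site)],
             times[which.max(prof$plasma)])
  expect_equal(prof$effect_site[1], 0)
  # constant plasma: Ce(t) = Cp (1 - exp(-ke0 t)); half rise at ln(2)/ke0
  const <- data.frame(time = seq(0, 200, 0.25), plasma = 100)
  ce_half <- effect_site_concentration(0.0065, log(2) / 0.0065,
                                       plasma = const)
  expect_equal(ce_half, 50, tolerance = 1e-4)
  expect_error(effect_site_concentration(-1, 1, plasma = const), "positive")
})

test_that("baseline age covariate and score model do the stated arithmetic", {
  expect_equal(baseline_with_age(48.51, 5, -0.21), 48.51)
  expect_equal(baseline_with_age(99, 8, 0), 99)
  expect_equal(baseline_with_age(48.51, 10, -0.21), 48.51 * 2^(-0.21))
  expect_error(baseline_with_age(48.51, -2, -0.21), "positive")
  expect_equal(score_model(48.51, 0.015, 0.0022, ce = 0, t = 0), 48.51)
  expect_equal(score_model(48.51, 0.015, 0.0022, ce = 0, t = 84), 49.77)
  # drug-attributable plus natural change over 12 weeks
  expect_equal(score_model(48.51, 0.015, 0.0022, ce = 500, t = 84) - 48.51,
               0.015 * 84 + 0.0022 * 500)
  expect_error(score_model(48, 0.015, 0.002, 0, t = -1), ">= 0")
})

test_that("equilibration half-life converts ke0 to weeks", {
  expect_equal(round(equilibration_half_life(0.0065)), 15)
  expect_equal(equilibration_half_life(log(2) / 7), 1)
  expect_equal(equilibration_half_life(0.010), log(2) / 0.010 / 7)
  expect_error(equilibration_half_life(0), "positive")
})
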