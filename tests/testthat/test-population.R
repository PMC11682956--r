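test_that("zero omegas give exactly zero etas and zero sigma passes scores through", {
  spec <- random_effect_spec(0, 0, 0, 0, 0, 0)
  e <- sample_etas(spec, 10, seed = 1)
  expect_true(all(as.matrix(e) == 0))
  expect_equal(add_residual(c(1, 2, 3), 0), c(1, 2, 3))
})

test_that("large-sample eta moments match the specification", {
  spec <- random_effect_spec()
  e <- sample_etas(spec, 2e5, seed = 10)
  expect_equal(cor(e$eta_e0, e$eta_kprog), 0.48, tolerance = 0.01 / 0.48)
  expect_equal(sd(e$eta_kprog), 0.018, tolerance = 0.0002 / 0.018)
  expect_equal(sd(e$eta_ke0), 0.21, tolerance = 0.01)
  expect_equal(sd(e$eta_deff), 1.4, tolerance = 0.01)
  expect_lt(abs(cor(e$eta_ke0, e$eta_deff)), 0.01)
  expect_lt(max(abs(colMeans(as.matrix(e)))), 0.01)
})

test_that("eta draws are reproducible given a seed and respect the covariance", {
  spec <- random_effect_spec()
  expect_identical(sample_etas(spec, 50, seed = 3), sample_etas(spec, 50, seed = 3))
  S <- eta_covariance(spec)
  expect_equal(S[2, 4], 0.48 * 0.2 * 0.018)
  expect_equal(diag(S), c(eta_ke0 = 0.21^2, eta_e0 = 0.2^2,
                          eta_deff = 1.4^2, eta_kprog = 0.018^2))
  expect_error(random_effect_spec(corr_e0_kprog = 1.4), "\\[-1, 1\\]")
})

test_that("individualize builds typical values at zero etas and admits negative slopes", {
  params <- final_params()
  zero <- tibble::tibble(eta_ke0 = 0, eta_e0 = 0, eta_deff = 0, eta_kprog = 0)
  ind <- individualize(params, zero, tibble::tibble(age = 5, weight = 70))
  expect_equal(ind$e0_i, 48.51)
  expect_equal(ind$ke0_i, 0.0065)
  expect_equal(ind$cl_i, 504)
  expect_equal(ind$v2_i, 40)
  neg <- individualize(params, tibble::tibble(eta_ke0 = 0, eta_e0 = 0,
                                              eta_deff = 0, eta_kprog = -0.03),
                       tibble::tibble(age = 5, weight = 20))
  expect_equal(neg$kprog_i, -0.015)
})

test_that("lognormal parameters stay positive and their median matches the typical value", {
  params <- final_params()
  etas <- sample_etas(params$ranef, 4e4, seed = 8)
  demog <- tibble::tibble(age = rep(5, 4e4), weight = rep(20, 4e4))
  ind <- individualize(params, etas, demog)
  expect_true(all(ind$ke0_i > 0 & ind$e0_i > 0 & ind$deff_i > 0))
  expect_equal(median(ind$e0_i) / 48.51, 1, tolerance = 0.01)
})

test_that("additive residual error has the specified moments", {
  pred <- rep(50, 1e5)
  obs <- add_residual(pred, 1.6, seed = 4)
  expect_equal(sd(obs - pred), 1.6, tolerance = 0.02 / 1.6)
  expect_equal(mean(obs - pred), 0, tolerance = 0.02)
  expect_identical(add_residual(pred, 1.6, seed = 4), obs)
  expect_error(add_residual(pred, -1), ">= 0")
})
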