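test_that("Laplace OFV matches brute-force integration on a one-eta toy problem", {
  ds <- toy_dataset()
  params <- model_parameters(ranef = random_effect_spec(0, 0.2, 0, 0, 0, 1.6))
  ofv <- neg2_loglik(params, ds)
  # independent oracle: quadrature of the marginal likelihood per subject
  pd <- params$pd
  ofv_int <- 0
  for (i in 1:3) {
    oi <- ds$observations[ds$observations$id == i, ]
    agei <- ds$demographics$age[i]
    lik <- stats::integrate(function(etas) vapply(etas, function(e) {
      f <- baseline_with_age(pd$e0, agei, pd$beta_age) * exp(e) +
        pd$kprog * oi$time
      prod(stats::dnorm(oi$score, f, 1.6)) * stats::dnorm(e, 0, 0.2)
    }, numeric(1)), -2, 2, rel.tol = 1e-10)$value
    ofv_int <- ofv_int - 2 * log(lik)
  }
  expect_equal(ofv, ofv_int, tolerance = 0.1 / ofv_int)
})

test_that("with all omegas zero the OFV is the Gaussian likelihood at typical predictions", {
  ds <- toy_dataset()
  params <- model_parameters(ranef = random_effect_spec(0, 0, 0, 0, 0, 1.6))
  pd <- params$pd
  pred <- baseline_with_age(pd$e0, ds$demographics$age[ds$observations$id],
                            pd$beta_age) + pd$kprog * ds$observations$time
  manual <- -2 * sum(stats::dnorm(ds$observations$score, pred, 1.6,
                                  log = TRUE))
  expect_equal(neg2_loglik(params, ds), manual)
})

test_that("a richer model never has a worse optimised fit than its nested reduction", {
  ds <- toy_dataset(sigma = 1.2, etas = c(0.2, -0.1, 0.12, -0.05),
                    seed = 77)
  # nested: beta_age fixed at 0 (covariate-free); full: beta_age estimated
  init0 <- model_parameters(pd = pd_parameters(beta_age = 0),
                            ranef = random_effect_spec(0, 0, 0, 0, 0, 0))
  f_red <- fit_pkpd(ds, init = init0, covariate_model = data.frame(),
                    compute_ofv = FALSE)
  f_full <- fit_pkpd(ds, init = init0, compute_ofv = FALSE)
  # both fits minimise a residual sum of squares; sigma_add = sqrt(RSS/N)
  expect_lte(f_full$sigma_add, f_red$sigma_add + 1e-8)
})

test_that("zero-noise zero-IIV data are inverted exactly by the least-squares path", {
  p0 <- model_parameters(ranef = random_effect_spec(0, 0, 0, 0, 0, 0))
  ds0 <- simulate_dataset(phase2_design(), p0, n = 30, seed = 5)
  init <- model_parameters(
    pd = pd_parameters(ke0 = 0.004, e0 = 55, beta_age = -0.1, deff = 0.004,
                       kprog = 0.01),
    ranef = random_effect_spec(0, 0, 0, 0, 0, 0))
  ft <- fit_pkpd(ds0, init = init)
  expect_equal(ft$method, "nls")
  expect_true(ft$converged)
  for (p in c("ke0", "e0", "deff", "kprog", "beta_age")) {
    truth <- c(ke0 = 0.0065, e0 = 48.51, deff = 0.0022, kprog = 0.015,
               beta_age = -0.21)[[p]]
    expect_equal(ft$estimates[[p]], truth, tolerance = 1e-4)
  }
  expect_lt(ft$sigma_add, 1e-5)
})

test_that("SAEM fits are reproducible given identical seed and options", {
  ds <- simulate_dataset(phase2_design(), final_params(), n = 20, seed = 13)
  ctrl <- saem_control(n_burn = 30, n_iter = 20, n_chains = 1)
  f1 <- fit_pkpd(ds, init = final_params(), control = ctrl, seed = 99,
                 compute_ofv = FALSE)
  f2 <- fit_pkpd(ds, init = final_params(), control = ctrl, seed = 99,
                 compute_ofv = FALSE)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$omega, f2$omega)
  expect_identical(f1$sigma_add, f2$sigma_add)
})

test_that("SAEM and the deterministic Laplace route agree on a small dataset", {
  params <- model_parameters(ranef = random_effect_spec(0, 0.2, 0, 0.018,
                                                        0.48, 1.6))
  ds <- simulate_dataset(phase2_design(), params, n = 14, seed = 6)
  fl <- fit_pkpd(ds, init = params, method = "laplace", compute_ofv = FALSE)
  fs <- fit_pkpd(ds, init = params, method = "saem", seed = 7,
                 control = saem_control(n_burn = 150, n_iter = 150,
                                        n_chains = 1), compute_ofv = FALSE)
  expect_true(fl$converged)
  expect_equal(fs$estimates[["e0"]], fl$estimates[["e0"]], tolerance = 0.02)
  expect_equal(fs$estimates[["ke0"]], fl$estimates[["ke0"]], tolerance = 0.1)
  expect_equal(fs$estimates[["deff"]], fl$estimates[["deff"]],
               tolerance = 0.1)
  expect_lt(abs(fs$estimates[["kprog"]] - fl$estimates[["kprog"]]), 0.005)
  expect_lt(abs(fs$sigma_add - fl$sigma_add), 0.4)
})

test_that("likelihood-ratio decisions follow the chi-square threshold", {
  d <- lrt_decision(100, 103.85, df = 1)
  expect_equal(d$decision, "accept_full")
  expect_equal(d$critical, stats::qchisq(0.95, 1))
  expect_equal(round(d$critical, 2), 3.84)
  d0 <- lrt_decision(100, 100, df = 1)
  expect_equal(d0$decision, "keep_reduced")
  expect_equal(d0$p_value, 1)
  # just under the critical value is not enough
  expect_equal(lrt_decision(100, 103.80, df = 1)$decision, "keep_reduced")
  expect_error(lrt_decision(100, 101, df = 0), ">= 1")
})

test_that("tidy and glance expose the fit in broom style", {
  ds <- simulate_dataset(phase2_design(), final_params(), n = 15, seed = 3)
  ft <- fit_pkpd(ds, init = final_params(), control = quick_control(),
                 seed = 3)
  td <- tidy(ft)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_true(all(c("ke0", "e0", "deff", "kprog", "beta_age", "sigma_add",
                    "corr_e0_kprog") %in% td$term))
  g <- glance(ft)
  expect_equal(g$n_subjects, 15)
  expect_equal(g$n_obs, 60)
  expect_true(is.finite(g$ofv))
})

test_that("forward selection retains a simulated age effect on the baseline", {
  params <- final_params() # simulated with beta_age = -0.21 on E0
  ds <- simulate_dataset(phase2_design(), params, n = 100, seed = 41)
  cand <- data.frame(param = "e0", covariate = "age")
  res <- covariate_search(ds, cand, init = perturbed_init(),
                          control = saem_control(n_burn = 150, n_iter = 150,
                                                 n_chains = 1), seed = 41)
  expect_false(is.null(res$selected))
  expect_equal(res$selected$covariate, "age")
  expect_true(all(c("forward", "backward") %in% res$log$phase))
  expect_lt(res$log$p_value[res$log$phase == "forward"][1], 0.05)
})

test_that("a null covariate is not retained", {
  # zero-IIV data keep both fits on the deterministic least-squares path,
  # so the OFV comparison is exact and the decision is a textbook LRT
  params <- model_parameters(ranef = random_effect_spec(0, 0, 0, 0, 0, 1.6))
  ds <- simulate_dataset(phase2_design(), params, n = 80, seed = 42)
  init <- model_parameters(ranef = random_effect_spec(0, 0, 0, 0, 0, 1.6))
  cand <- data.frame(param = "e0", covariate = "sex") # never simulated
  res <- covariate_search(ds, cand, init = init, seed = 42)
  expect_true(is.null(res$selected) || nrow(res$selected) == 0)
  expect_gt(res$log$p_value[1], 0.05)
})

test_that("case bootstrap reduces to the original fit without resampling and summarises replicates", {
  ds <- simulate_dataset(phase2_design(), final_params(), n = 25, seed = 14)
  seed1 <- withr::with_seed(5, sample.int(2^30, 1))
  bt <- bootstrap_fit(ds, n_runs = 1, init = final_params(), seed = 5,
                      resample = FALSE, control = quick_control(),
                      method = "saem")
  ft <- fit_pkpd(ds, init = final_params(), seed = seed1,
                 control = quick_control(), compute_ofv = FALSE)
  ref <- tidy(ft)
  expect_equal(bt$n_converged, 1)
  merged <- merge(bt$replicates, ref, by = "term")
  expect_equal(merged$estimate.x, merged$estimate.y)
  bt3 <- bootstrap_fit(ds, n_runs = 3, init = final_params(), seed = 6,
                       control = quick_control())
  expect_true(all(bt3$summary$q2.5 <= bt3$summary$median &
                    bt3$summary$median <= bt3$summary$q97.5))
  expect_gte(bt3$n_converged, 2)
})
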