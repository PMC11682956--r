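# shared fixtures built in code

# published final PD estimates with the package's placeholder PK
final_params <- function() model_parameters()

# a deliberately perturbed starting point for simulate-then-recover runs
perturbed_init <- function() {
  model_parameters(
    pd = pd_parameters(ke0 = 0.01, e0 = 44, beta_age = -0.1,
                       deff = 0.001, kprog = 0.02),
    ranef = random_effect_spec(omega_ke0 = 0.3, omega_e0 = 0.3,
                               omega_deff = 1.0, omega_kprog = 0.03,
                               corr_e0_kprog = 0.2, sigma_add = 2.5)
  )
}

# short SAEM schedule for smoke-level fits
quick_control <- function() {
  saem_control(n_burn = 60, n_iter = 60, n_chains = 1)
}

# hand-built tiny placebo-style dataset with no dosing rows
toy_dataset <- function(sigma = 1.5, etas = c(0.1, -0.15, 0.05),
                        seed = 42) {
  n <- length(etas)
  demog <- tibble::tibble(id = seq_len(n),
                          age = seq(4, 9, length.out = n),
                          weight = seq(16, 28, length.out = n),
                          sex = "male", arm = "placebo")
  obs <- tidyr::expand_grid(id = seq_along(etas), time = c(0, 28, 56, 84))
  pd <- pd_parameters()
  pred <- baseline_with_age(pd$e0, demog$age[obs$id], pd$beta_age) *
    exp(etas[obs$id]) + pd$kprog * obs$time
  obs$score <- pred + withr::with_seed(seed, stats::rnorm(nrow(obs), 0, sigma))
  obs$missing <- FALSE
  structure(list(
    demographics = demog,
    dosing = tibble::tibble(id = integer(), start = numeric(),
                            amount_mg = numeric(), duration = numeric()),
    observations = obs
  ), class = "trial_dataset")
}
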