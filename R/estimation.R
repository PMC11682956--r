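#' Objective function value (-2 log marginal likelihood)
#'
#' Computes the OFV of the score model for a dataset at given parameter
#' values, with the subject-level random effects integrated out by the
#' Laplace approximation (per-subject mode finding plus a numerical
#' Hessian). When all omegas are zero the marginal likelihood is the plain
#' Gaussian likelihood at the typical predictions and is computed in closed
#' form. PK parameters are fixed and allometrically scaled to each
#' subject's weight.
#'
#' @param params A [model_parameters()] object (PD fixed effects, random
#'   effects and residual SD to evaluate; `params$pk` supplies the fixed
#'   PK).
#' @param dataset A `trial_dataset`.
#' @param covariate_model Covariate terms as a data frame with columns
#'   `param`, `covariate`, `ref`; defaults to age on `e0` normalised at
#'   `params$pd$age_ref`.
#' @return The OFV (a single number).
#' @examples
#' \donttest{
#' ds <- simulate_dataset(phase2_design(), model_parameters(), n = 20, seed = 1)
#' neg2_loglik(model_parameters(), ds)
#' }
#' @export
neg2_loglik <- function(params, dataset,
                        covariate_model = .default_covmodel(params$pd$age_ref)) {
  stopifnot(inherits(params, "model_parameters"))
  prob <- .prepare_problem(dataset, params$pk, covariate_model)
  om <- c(params$ranef$omega_ke0, params$ranef$omega_e0,
          params$ranef$omega_deff, params$ranef$omega_kprog)
  theta <- .estimates_to_theta(params$pd, covariate_model)
  .laplace_ofv(prob, theta, om, params$ranef$corr_e0_kprog,
               params$ranef$sigma_add)
}

#' Fit the population PD model by nonlinear mixed effects
#'
#' Maximises the marginal likelihood of the effect-compartment score model
#' over the PD fixed effects, the random-effect SDs (with the `e0`--`kprog`
#' correlation) and the additive residual SD, holding the PK parameters
#' fixed (allometrically scaled per subject). `method = "saem"` is the
#' primary stochastic approximation EM estimator (MCMC conditional sampling
#' of the etas, closed-form sufficient-statistic updates);
#' `method = "laplace"` performs deterministic outer optimisation of the
#' Laplace OFV and is practical for small datasets. Random effects whose
#' initial omega is zero are held fixed at zero (the corresponding variance
#' is not estimated); if all omegas are zero the fit reduces to nonlinear
#' least squares on the fixed effects.
#'
#' @param dataset A `trial_dataset` (see [simulate_dataset()] or
#'   [read_trial_dataset()]).
#' @param init A [model_parameters()] with initial values (also carries the
#'   fixed PK); `NULL` uses [moment_init()].
#' @param method `"saem"` or `"laplace"`.
#' @param control A [saem_control()] (SAEM only).
#' @param covariate_model Covariate terms (see [neg2_loglik()]).
#' @param estimate_corr Estimate the `e0`--`kprog` eta correlation
#'   (`TRUE`), or hold it at its initial value.
#' @param compute_ofv Evaluate the Laplace OFV at the final estimates.
#' @param polish_sigma After SAEM, replace the residual SD by its profile
#'   maximum-likelihood value given the other estimates (a short 1-D
#'   optimisation of the Laplace OFV). The sigma component of the EM map
#'   contracts slowly on sparse designs, so this removes the slowest part
#'   of the stochastic convergence at modest cost.
#' @param seed Integer seed making SAEM reproducible.
#' @return An object of class `pkpd_fit`; see [tidy.pkpd_fit()] and
#'   [glance.pkpd_fit()].
#' @examples
#' \donttest{
#' ds <- simulate_dataset(phase2_design(), model_parameters(), n = 40, seed = 2)
#' ft <- fit_pkpd(ds, init = model_parameters(), seed = 2,
#'                control = saem_control(n_burn = 50, n_iter = 30,
#'                                       n_chains = 1),
#'                compute_ofv = FALSE)
#' tidy(ft)
#' }
#' @export
fit_pkpd <- function(dataset, init = NULL, method = c("saem", "laplace"),
                     control = saem_control(),
                     covariate_model = NULL,
                     estimate_corr = TRUE, compute_ofv = TRUE,
                     polish_sigma = TRUE, seed = NULL) {
  method <- match.arg(method)
  if (is.null(init)) init <- moment_init(dataset)
  stopifnot(inherits(init, "model_parameters"))
  if (is.null(covariate_model)) {
    covariate_model <- .default_covmodel(init$pd$age_ref)
  }
  prob <- .prepare_problem(dataset, init$pk, covariate_model)
  theta0 <- .estimates_to_theta(init$pd, covariate_model)
  om0 <- c(init$ranef$omega_ke0, init$ranef$omega_e0,
           init$ranef$omega_deff, init$ranef$omega_kprog)
  corr0 <- init$ranef$corr_e0_kprog
  sigma0 <- init$ranef$sigma_add
  t0 <- proc.time()[["elapsed"]]
  if (all(om0 == 0)) {
    res <- .fit_nls(prob, theta0)
  } else if (method == "saem") {
    run <- function() .saem(prob, theta0, om0, corr0, sigma0, control,
                            estimate_corr)
    res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  } else {
    res <- .fit_laplace_outer(prob, theta0, om0, corr0, sigma0,
                              estimate_corr)
  }
  if (polish_sigma && method == "saem" && any(om0 > 0) && res$converged) {
    res$sigma <- .profile_sigma(prob, res$theta, res$om, res$corr,
                                res$sigma)
  }
  ofv <- NA_real_
  if (compute_ofv && res$converged) {
    ofv <- tryCatch(
      .laplace_ofv(prob, res$theta, res$om, res$corr, res$sigma),
      error = function(e) NA_real_)
  }
  structure(list(
    estimates = .theta_to_estimates(res$theta, prob$design$theta_names),
    omega = stats::setNames(res$om, paste0("omega_", .dim_names)),
    corr_e0_kprog = res$corr, sigma_add = res$sigma,
    theta = res$theta, ofv = ofv, converged = res$converged,
    trace = res$trace, method = if (all(om0 == 0)) "nls" else method,
    control = control, covariate_model = covariate_model,
    fixed_pk = init$pk, n_subjects = prob$n, n_obs = prob$N,
    seed = seed, runtime = proc.time()[["elapsed"]] - t0,
    se = NULL, dataset = dataset
  ), class = "pkpd_fit")
}

# profile MLE of sigma given the other estimates: 1-D minimisation of the
# Laplace OFV on the log scale, warm-starting the per-subject eta modes
# across evaluations
.profile_sigma <- function(prob, theta, om, corr, sigma) {
  cache <- new.env()
  cache$modes <- NULL
  f <- function(ls) {
    res <- tryCatch(
      .laplace_ofv(prob, theta, om, corr, exp(ls), modes = cache$modes,
                   return_modes = TRUE),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    cache$modes <- res$modes
    res$ofv
  }
  opt <- stats::optimize(f, interval = log(sigma) + c(-1.5, 1.5),
                         tol = 0.005)
  exp(opt$minimum)
}

# nonlinear least squares over fixed effects (all omegas zero); the sigma
# MLE is then RSS/N
.fit_nls <- function(prob, theta0) {
  obj <- function(th) {
    mu <- .mu_matrix(prob$design, th)
    pr <- .predict_rows(prob, mu)
    sum((prob$y - pr$f)^2)
  }
  opt <- stats::nlminb(theta0, obj, control = list(eval.max = 2000,
                                                   iter.max = 1000))
  sig <- sqrt(opt$objective / prob$N)
  list(theta = opt$par, om = rep(0, 4), corr = 0, sigma = sig,
       trace = NULL, eta = NULL, converged = opt$convergence == 0)
}

# deterministic outer optimisation of the Laplace OFV on a transformed
# scale (log for positive quantities, atanh for the correlation); modes are
# warm-started across evaluations
.fit_laplace_outer <- function(prob, theta0, om0, corr0, sigma0,
                               estimate_corr) {
  act <- which(om0 > 0)
  use_corr <- estimate_corr && all(c(2, 4) %in% act)
  pack <- function(theta, om, corr, sigma) {
    c(theta, log(om[act]), if (use_corr) atanh(corr), log(sigma))
  }
  p <- length(theta0)
  unpack <- function(v) {
    theta <- v[seq_len(p)]
    om <- rep(0, 4)
    om[act] <- exp(v[p + seq_along(act)])
    j <- p + length(act)
    corr <- if (use_corr) tanh(v[j + 1]) else corr0
    sigma <- exp(v[length(v)])
    list(theta = theta, om = om, corr = corr, sigma = sigma)
  }
  cache <- new.env()
  cache$modes <- NULL
  obj <- function(v) {
    u <- unpack(v)
    res <- tryCatch(
      .laplace_ofv(prob, u$theta, u$om, u$corr, u$sigma,
                   modes = cache$modes, return_modes = TRUE),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    cache$modes <- res$modes
    res$ofv
  }
  opt <- stats::nlminb(pack(theta0, om0, corr0, sigma0), obj,
                       control = list(eval.max = 2000, iter.max = 300,
                                      rel.tol = 1e-8))
  ok <- is.finite(opt$objective) &&
    (opt$convergence == 0 ||
       grepl("relative convergence|absolute function convergence|X-convergence",
             opt$message %||% ""))
  if (is.finite(opt$objective) && !ok) {
    # "false convergence" is common here because the warm-started inner
    # modes make the objective slightly nonsmooth; a restart that cannot
    # improve the optimum confirms we are at a genuine minimum
    opt2 <- stats::nlminb(opt$par, obj,
                          control = list(eval.max = 500, iter.max = 100))
    if (is.finite(opt2$objective) &&
        opt2$objective <= opt$objective + 1e-8) {
      ok <- opt$objective - opt2$objective < 0.1
      opt <- opt2
    }
  }
  u <- unpack(opt$par)
  list(theta = u$theta, om = u$om, corr = u$corr, sigma = u$sigma,
       trace = NULL, eta = NULL, converged = ok)
}

#' Method-of-moments initial values from a dataset
#'
#' Builds starting values for [fit_pkpd()] from the data: `e0`, `beta_age`
#' and `omega_e0` from a log-log regression of baseline scores on age;
#' `kprog` and `omega_kprog` from the pre-crossover placebo slopes; generic
#' moderate starting values for the exposure-related parameters.
#'
#' @param dataset A `trial_dataset`.
#' @param pk Fixed PK parameters to attach.
#' @return A [model_parameters()] object.
#' @export
moment_init <- function(dataset, pk = pk_parameters()) {
  dm <- dataset$demographics
  obs <- dataset$observations
  base <- obs[obs$time == 0 & !obs$missing & !is.na(obs$score), ]
  base <- dplyr::left_join(base, dm, by = "id")
  fit0 <- stats::lm(log(pmax(score, 1)) ~ log(age / 5), data = base)
  e0 <- exp(stats::coef(fit0)[[1]])
  beta_age <- stats::coef(fit0)[[2]]
  omega_e0 <- max(stats::sd(stats::residuals(fit0)), 0.05)
  plc <- dm$id[dm$arm == "placebo"]
  slopes <- vapply(plc, function(id) {
    oi <- obs[obs$id == id & obs$time <= 84 & !obs$missing &
                !is.na(obs$score), ]
    if (nrow(oi) < 2) return(NA_real_)
    stats::coef(stats::lm(score ~ time, data = oi))[[2]]
  }, numeric(1))
  slopes <- slopes[is.finite(slopes)]
  kprog <- if (length(slopes)) mean(slopes) else 0.01
  omega_kprog <- if (length(slopes) > 3) {
    max(stats::sd(slopes) / 2, 0.005)
  } else 0.01
  model_parameters(
    pk = pk,
    pd = pd_parameters(ke0 = 0.01, e0 = e0, beta_age = beta_age,
                       deff = 1e-3, kprog = kprog),
    ranef = random_effect_spec(omega_ke0 = 0.3, omega_e0 = omega_e0,
                               omega_deff = 1, omega_kprog = omega_kprog,
                               corr_e0_kprog = 0.3, sigma_add = 2)
  )
}

#' @export
print.pkpd_fit <- function(x, ...) {
  cat("<pkpd_fit>", x$method, "fit:", x$n_subjects, "subjects,",
      x$n_obs, "observations\n")
  cat("converged:", x$converged,
      if (is.finite(x$ofv)) paste(" OFV:", round(x$ofv, 2)) else "", "\n")
  print(tidy(x), n = 20)
  invisible(x)
}

#' Turn a fit into a tidy coefficient table
#'
#' @param x A `pkpd_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, and when standard
#'   errors have been computed (see [fit_standard_errors()]) `std_error`
#'   and `rse_pct`.
#' @export
tidy.pkpd_fit <- function(x, ...) {
  est <- c(x$estimates,
           x$omega[x$omega > 0 | names(x$omega) == "omega_kprog"],
           corr_e0_kprog = x$corr_e0_kprog, sigma_add = x$sigma_add)
  out <- tibble::tibble(term = names(est), estimate = unname(est))
  if (!is.null(x$se)) {
    out <- dplyr::left_join(out, x$se, by = "term")
  }
  out
}

#' One-row fit summary
#'
#' @param x A `pkpd_fit`.
#' @param ... Unused.
#' @return A tibble with `ofv`, `n_subjects`, `n_obs`, `method`,
#'   `converged`, `runtime_s`.
#' @export
glance.pkpd_fit <- function(x, ...) {
  tibble::tibble(ofv = x$ofv, n_subjects = x$n_subjects, n_obs = x$n_obs,
                 method = x$method, converged = x$converged,
                 runtime_s = x$runtime)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Standard errors from the numerical information matrix
#'
#' Central-difference Hessian of the Laplace OFV at the estimates on the
#' transformed scale (log for positive parameters, atanh for the
#' correlation), inverted to a covariance matrix and mapped back by the
#' delta method. RSE% is `100 * SE / |estimate|`. Quadratic in the number
#' of parameters and a full Laplace evaluation per Hessian entry, so
#' intended for small-to-moderate datasets.
#'
#' @param fit A `pkpd_fit`.
#' @param rel_step Relative step size of the central differences.
#' @return The fit with its `se` slot filled (also returned by
#'   [tidy.pkpd_fit()]).
#' @export
fit_standard_errors <- function(fit, rel_step = 1e-3) {
  prob <- .prepare_problem(fit$dataset, fit$fixed_pk, fit$covariate_model)
  act <- which(fit$omega > 0)
  use_corr <- all(c(2, 4) %in% act)
  p <- length(fit$theta)
  v0 <- c(fit$theta, log(fit$omega[act]),
          if (use_corr) atanh(fit$corr_e0_kprog), log(fit$sigma_add))
  npar <- length(v0)
  cache <- new.env(); cache$modes <- NULL
  f <- function(v) {
    om <- rep(0, 4); om[act] <- exp(v[p + seq_along(act)])
    corr <- if (use_corr) tanh(v[p + length(act) + 1]) else fit$corr_e0_kprog
    res <- .laplace_ofv(prob, v[seq_len(p)], om, corr, exp(v[npar]),
                        modes = cache$modes, return_modes = TRUE)
    cache$modes <- res$modes
    res$ofv
  }
  h <- pmax(abs(v0), 0.1) * rel_step
  H <- matrix(0, npar, npar)
  f0 <- f(v0)
  fp <- numeric(npar); fm <- numeric(npar)
  for (a in seq_len(npar)) {
    ea <- numeric(npar); ea[a] <- h[a]
    fp[a] <- f(v0 + ea); fm[a] <- f(v0 - ea)
    H[a, a] <- (fp[a] - 2 * f0 + fm[a]) / h[a]^2
  }
  for (a in seq_len(npar - 1)) {
    for (b in (a + 1):npar) {
      ea <- numeric(npar); ea[a] <- h[a]
      eb <- numeric(npar); eb[b] <- h[b]
      H[a, b] <- H[b, a] <-
        (f(v0 + ea + eb) - fp[a] - fp[b] + 2 * f0 -
           f(v0 - ea - eb) + fm[a] + fm[b]) / (2 * h[a] * h[b])
    }
  }
  # OFV = -2 logL, so the observed information is H/2
  V <- tryCatch(solve(H / 2), error = function(e) matrix(NA, npar, npar))
  se_trans <- sqrt(pmax(diag(V), 0))
  # delta method back to the natural scale
  nat <- c(fit$estimates, fit$omega[act],
           if (use_corr) fit$corr_e0_kprog, fit$sigma_add)
  deriv <- c(abs(.theta_deriv(fit$theta, fit$covariate_model)),
             fit$omega[act],
             if (use_corr) 1 - fit$corr_e0_kprog^2, fit$sigma_add)
  se_nat <- se_trans * deriv
  terms <- c(names(fit$estimates), names(fit$omega)[act],
             if (use_corr) "corr_e0_kprog", "sigma_add")
  fit$se <- tibble::tibble(term = terms, std_error = se_nat,
                           rse_pct = 100 * se_nat / abs(nat))
  fit
}

# d(natural)/d(transformed) for the fixed-effect vector: exp() for the three
# log-scale intercepts, identity elsewhere
.theta_deriv <- function(theta, covmodel) {
  d <- rep(1, length(theta))
  d[1:3] <- exp(theta[1:3])
  d
}

#' Likelihood-ratio decision between nested models
#'
#' Chi-square test on the OFV difference between a full and a reduced
#' (nested) model: the full model is accepted when the OFV drops by more
#' than the chi-square critical value (3.84 for one degree of freedom at
#' alpha 0.05).
#'
#' @param ofv_full,ofv_reduced OFVs at the respective optima.
#' @param df Degrees-of-freedom difference (>= 1).
#' @param alpha Significance level.
#' @return A tibble with `delta_ofv`, `df`, `critical`, `p_value`,
#'   `decision` (`"accept_full"` or `"keep_reduced"`).
#' @examples
#' lrt_decision(100, 103.85, df = 1)
#' @export
lrt_decision <- function(ofv_full, ofv_reduced, df = 1, alpha = 0.05) {
  if (df < 1) stop("lrt_decision: `df` must be >= 1", call. = FALSE)
  if (ofv_reduced < ofv_full - 1e-6) {
    warning("lrt_decision: reduced model has lower OFV than the full model")
  }
  delta <- max(ofv_reduced - ofv_full, 0)
  crit <- stats::qchisq(1 - alpha, df)
  tibble::tibble(
    delta_ofv = delta, df = df, critical = crit,
    p_value = stats::pchisq(delta, df, lower.tail = FALSE),
    decision = if (delta > crit) "accept_full" else "keep_reduced"
  )
}

#' Stepwise covariate selection by likelihood ratio
#'
#' Forward selection (default p < 0.05) followed by backward elimination
#' (default p < 0.01) over candidate covariate--parameter pairs.
#' Continuous covariates enter as power functions normalised to the dataset
#' median; `sex` enters as an indicator. Each candidate model is fitted
#' with [fit_pkpd()] and compared by Laplace OFV.
#'
#' @param dataset A `trial_dataset`.
#' @param candidates Data frame with columns `param` and `covariate`
#'   listing candidate pairs.
#' @param init Initial [model_parameters()] (also sets the fixed PK).
#' @param forward_alpha,backward_alpha Entry and retention thresholds.
#' @param base_covariates Covariate terms always present (default none).
#' @param ... Passed to [fit_pkpd()] (e.g. `control`, `method`, `seed`).
#' @return A list with `selected` (the retained covariate model),
#'   `fit` (final fit) and `log` (tibble of every step's decision).
#' @export
covariate_search <- function(dataset, candidates,
                             init = moment_init(dataset),
                             forward_alpha = 0.05, backward_alpha = 0.01,
                             base_covariates = NULL, ...) {
  if (!nrow(candidates)) stop("covariate_search: empty candidate list",
                              call. = FALSE)
  dm <- dataset$demographics
  ref_of <- function(cv) {
    if (cv == "sex") NA_real_ else stats::median(dm[[cv]], na.rm = TRUE)
  }
  candidates$ref <- vapply(candidates$covariate, ref_of, numeric(1))
  current <- base_covariates
  none <- candidates[0, ]
  fit_model <- function(cm) {
    fit_pkpd(dataset, init = init, covariate_model = cm %||% none, ...)
  }
  current_fit <- fit_model(current)
  log_rows <- list()
  repeat { # forward
    pool <- dplyr::anti_join(candidates,
                             current %||% candidates[0, ],
                             by = c("param", "covariate"))
    if (!nrow(pool)) break
    best <- NULL
    for (k in seq_len(nrow(pool))) {
      cand <- dplyr::bind_rows(current, pool[k, ])
      ft <- fit_model(cand)
      dec <- lrt_decision(ft$ofv, current_fit$ofv, df = 1,
                          alpha = forward_alpha)
      log_rows[[length(log_rows) + 1]] <- tibble::tibble(
        phase = "forward", param = pool$param[k],
        covariate = pool$covariate[k], ofv = ft$ofv,
        delta_ofv = dec$delta_ofv, p_value = dec$p_value,
        decision = dec$decision)
      if (dec$decision == "accept_full" &&
          (is.null(best) || ft$ofv < best$fit$ofv)) {
        best <- list(cm = cand, fit = ft)
      }
    }
    if (is.null(best)) break
    current <- best$cm
    current_fit <- best$fit
  }
  repeat { # backward at the stricter threshold
    if (is.null(current) || !nrow(current)) break
    worst <- NULL
    for (k in seq_len(nrow(current))) {
      cand <- current[-k, ]
      ft <- fit_model(if (nrow(cand)) cand else NULL)
      dec <- lrt_decision(current_fit$ofv, ft$ofv, df = 1,
                          alpha = backward_alpha)
      log_rows[[length(log_rows) + 1]] <- tibble::tibble(
        phase = "backward", param = current$param[k],
        covariate = current$covariate[k], ofv = ft$ofv,
        delta_ofv = dec$delta_ofv, p_value = dec$p_value,
        decision = dec$decision)
      if (dec$decision == "keep_reduced" &&
          (is.null(worst) || ft$ofv < worst$fit$ofv)) {
        worst <- list(cm = if (nrow(cand)) cand else NULL, fit = ft)
      }
    }
    if (is.null(worst)) break
    current <- worst$cm
    current_fit <- worst$fit
  }
  list(selected = current, fit = current_fit,
       log = dplyr::bind_rows(log_rows))
}

#' Case bootstrap of the model fit
#'
#' Resamples subjects with replacement, refits each replicate and
#' summarises the replicate estimates by their median and 2.5/97.5
#' percentiles.
#'
#' @param dataset A `trial_dataset`.
#' @param n_runs Number of bootstrap replicates.
#' @param init Initial [model_parameters()].
#' @param seed Integer seed (drives both the resampling and the SAEM runs).
#' @param resample Set `FALSE` to refit the original data in every
#'   replicate (degenerate bootstrap, useful for reproducibility checks).
#' @param ... Passed to [fit_pkpd()].
#' @return A list with `replicates` (tibble of per-replicate estimates),
#'   `summary` (median and percentile interval per parameter) and
#'   `n_converged`.
#' @export
bootstrap_fit <- function(dataset, n_runs = 200, init = NULL, seed = 1,
                          resample = TRUE, ...) {
  if (n_runs < 1) stop("bootstrap_fit: `n_runs` must be >= 1", call. = FALSE)
  dm <- dataset$demographics
  n <- nrow(dm)
  reps <- vector("list", n_runs)
  seeds <- withr::with_seed(seed, sample.int(2^30, n_runs))
  for (r in seq_len(n_runs)) {
    ids <- if (resample) {
      withr::with_seed(seeds[r], sample(dm$id, n, replace = TRUE))
    } else dm$id
    bds <- .resample_dataset(dataset, ids)
    ft <- tryCatch(
      fit_pkpd(bds, init = init, seed = seeds[r], compute_ofv = FALSE, ...),
      error = function(e) NULL)
    if (!is.null(ft) && ft$converged) {
      td <- tidy(ft)
      reps[[r]] <- tibble::tibble(run = r, term = td$term,
                                  estimate = td$estimate)
    }
  }
  replicates <- dplyr::bind_rows(reps)
  summary <- replicates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      median = stats::median(.data$estimate),
      q2.5 = stats::quantile(.data$estimate, 0.025),
      q97.5 = stats::quantile(.data$estimate, 0.975),
      .groups = "drop")
  list(replicates = replicates, summary = summary,
       n_converged = length(unique(replicates$run)))
}

# rebuild a trial_dataset from a resampled id vector (duplicates get fresh
# sequential ids)
.resample_dataset <- function(dataset, ids) {
  dm <- dataset$demographics
  new_dm <- dm[match(ids, dm$id), ]
  new_dm$id <- seq_along(ids)
  dose <- lapply(seq_along(ids), function(j) {
    d <- dataset$dosing[dataset$dosing$id == ids[j], ]
    d$id <- j
    d
  })
  obs <- lapply(seq_along(ids), function(j) {
    o <- dataset$observations[dataset$observations$id == ids[j], ]
    o$id <- j
    o
  })
  structure(list(demographics = new_dm, dosing = dplyr::bind_rows(dose),
                 observations = dplyr::bind_rows(obs)),
            class = "trial_dataset", design = attr(dataset, "design"))
}
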