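#' Goodness-of-fit table
#'
#' Per-observation predictions and residuals for a fitted model: population
#' predictions (`pred`, all etas zero), individual predictions (`ipred`,
#' empirical-Bayes eta modes) and individual weighted residuals
#' `iwres = (obs - ipred) / sigma`. With `sigma = 0` the IWRES column is
#' `NA` and flagged.
#'
#' @param dataset A `trial_dataset`.
#' @param fit A `pkpd_fit` (or a [model_parameters()] object, in which case
#'   those values are used as the "fit").
#' @return A tibble with columns `id`, `time`, `observed`, `pred`, `ipred`,
#'   `iwres`.
#' @export
gof_table <- function(dataset, fit) {
  pr <- .fit_problem_params(dataset, fit)
  prob <- pr$prob
  mu <- .mu_matrix(prob$design, pr$theta)
  pop <- .predict_rows(prob, mu)$f
  eta <- .eb_modes(prob, pr$theta, pr$om, pr$corr, pr$sigma)
  ind <- .predict_rows(prob, mu + eta)$f
  iwres <- if (pr$sigma > 0) (prob$y - ind) / pr$sigma else NA_real_
  if (pr$sigma == 0) {
    warning("gof_table: sigma is zero; IWRES undefined", call. = FALSE)
  }
  tibble::tibble(id = dataset$demographics$id[prob$subj], time = prob$t,
                 observed = prob$y, pred = pop, ipred = ind, iwres = iwres)
}

# accept either a pkpd_fit or model_parameters and return the pieces the
# diagnostics need
.fit_problem_params <- function(dataset, fit) {
  if (inherits(fit, "pkpd_fit")) {
    prob <- .prepare_problem(dataset, fit$fixed_pk, fit$covariate_model)
    list(prob = prob, theta = fit$theta, om = unname(fit$omega),
         corr = fit$corr_e0_kprog, sigma = fit$sigma_add)
  } else if (inherits(fit, "model_parameters")) {
    cm <- .default_covmodel(fit$pd$age_ref)
    prob <- .prepare_problem(dataset, fit$pk, cm)
    list(prob = prob, theta = .estimates_to_theta(fit$pd, cm),
         om = c(fit$ranef$omega_ke0, fit$ranef$omega_e0,
                fit$ranef$omega_deff, fit$ranef$omega_kprog),
         corr = fit$ranef$corr_e0_kprog, sigma = fit$ranef$sigma_add)
  } else {
    stop("expected a `pkpd_fit` or `model_parameters` object", call. = FALSE)
  }
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the dataset's own design and
#' demographics, prediction-corrects both observed and simulated scores
#' (additively, matching the additive error model: the bin-median
#' population prediction replaces each row's own population prediction) and
#' summarises the 5/50/95 percentiles per time bin together with
#' simulation-based confidence envelopes.
#'
#' @param dataset A `trial_dataset`; its design attribute supplies the
#'   regimen rules for re-simulation.
#' @param params A [model_parameters()] to simulate from (typically the
#'   fitted values).
#' @param n_sim Number of simulated replicate datasets.
#' @param bins Time-bin edges assigning observations to bins; defaults to
#'   the distinct observation times (one bin per nominal visit day).
#' @param seed Integer seed.
#' @param ci Envelope coverage (default 0.95).
#' @return An object of class `vpc_summary`: a tibble with one row per
#'   (bin, percentile): observed percentile, simulated median of that
#'   percentile and envelope bounds, plus `n_sim` as an attribute.
#' @export
pc_vpc <- function(dataset, params, n_sim = 500, bins = NULL, seed = 1,
                   ci = 0.95) {
  stopifnot(inherits(params, "model_parameters"))
  if (n_sim < 1) stop("pc_vpc: `n_sim` must be >= 1", call. = FALSE)
  design <- attr(dataset, "design")
  if (is.null(design)) design <- phase2_design()
  cm <- .default_covmodel(params$pd$age_ref)
  prob <- .prepare_problem(dataset, params$pk, cm)
  theta <- .estimates_to_theta(params$pd, cm)
  mu <- .mu_matrix(prob$design, theta)
  pred <- .predict_rows(prob, mu)$f
  times <- prob$t
  bin_id <- if (is.null(bins)) {
    match(times, sort(unique(times)))
  } else {
    findInterval(times, sort(bins))
  }
  bin_id <- match(bin_id, sort(unique(bin_id)))
  bin_f <- factor(bin_id, levels = sort(unique(bin_id)))
  bin_pred <- stats::ave(pred, bin_id, FUN = stats::median)
  pcorr <- function(y) y - pred + bin_pred
  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- vapply(split(pcorr(prob$y), bin_f), stats::quantile,
                    numeric(3), probs = probs)
  dm <- dataset$demographics
  sim_pct <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      etas <- sample_etas(params$ranef, prob$n)
      phi <- mu + as.matrix(etas)[, c(1, 2, 3, 4)] # ke0, e0, deff, kprog
      f <- .predict_rows(prob, phi)$f
      ysim <- f + stats::rnorm(prob$N, 0, params$ranef$sigma_add)
      vapply(split(pcorr(ysim), bin_f), stats::quantile, numeric(3),
             probs = probs)
    }, obs_pct)
  })
  alpha <- (1 - ci) / 2
  nb <- dim(obs_pct)[2]
  out <- tidyr::expand_grid(bin = seq_len(nb), percentile = probs * 100)
  get_stat <- function(f) {
    as.vector(apply(sim_pct, c(1, 2), f)) # percentile-major within bin
  }
  out$observed <- as.vector(obs_pct)
  out$simulated <- get_stat(stats::median)
  out$env_lo <- as.vector(apply(sim_pct, c(1, 2), stats::quantile,
                                probs = alpha))
  out$env_hi <- as.vector(apply(sim_pct, c(1, 2), stats::quantile,
                                probs = 1 - alpha))
  out$bin_time <- vapply(split(times, bin_f), stats::median,
                         numeric(1))[out$bin]
  structure(out, class = c("vpc_summary", class(out)), n_sim = n_sim)
}

#' Plot a prediction-corrected VPC
#'
#' @param object A `vpc_summary` from [pc_vpc()].
#' @param ... Unused.
#' @return A ggplot: observed percentiles (lines/points) over the simulated
#'   envelopes (ribbons) per time bin.
#' @export
autoplot.vpc_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_time,
                                       group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$env_lo,
                                      ymax = .data$env_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$simulated),
                       colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "Time (days)",
                  y = "Prediction-corrected score",
                  title = "Prediction-corrected visual predictive check",
                  subtitle = paste(attr(object, "n_sim"),
                                   "simulated datasets; 5/50/95 percentiles"))
}

#' Goodness-of-fit panel plots
#'
#' @param gof A tibble from [gof_table()].
#' @return A ggplot with observations against population and individual
#'   predictions and IWRES over time.
#' @export
plot_gof <- function(gof) {
  long <- tidyr::pivot_longer(gof, c("pred", "ipred"),
                              names_to = "type", values_to = "prediction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$prediction,
                                     y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::facet_wrap(~type) +
    ggplot2::labs(x = "Prediction", y = "Observed score")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
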