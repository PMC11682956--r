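#' Allometric scaling of a pharmacokinetic parameter
#'
#' Scales a parameter defined at a reference body weight to an individual's
#' weight with a power law, `value_ref * (weight / ref_weight)^exponent`.
#' By convention clearances use exponent 0.75 and volumes exponent 1.
#'
#' @param value_ref Parameter value at the reference weight.
#' @param weight Individual body weight, kg (vectorised).
#' @param exponent Allometric exponent.
#' @param ref_weight Reference body weight, kg.
#' @return The scaled parameter value(s).
#' @examples
#' allometric_scale(504, weight = 20.5, exponent = 0.75, ref_weight = 70)
#' @export
allometric_scale <- function(value_ref, weight, exponent, ref_weight = 70) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("allometric_scale: `weight` must be positive", call. = FALSE)
  }
  if (!is.finite(ref_weight) || ref_weight <= 0) {
    stop("allometric_scale: `ref_weight` must be positive", call. = FALSE)
  }
  value_ref * (weight / ref_weight)^exponent
}

#' Scale PK parameters to an individual body weight
#'
#' Applies [allometric_scale()] to the clearances (`cl_f`, `q_f`; exponent
#' `exp_cl`) and volumes (`v1_f`, `v2_f`; exponent `exp_v`) of a
#' [pk_parameters()] object.
#'
#' @param pk A [pk_parameters()] object (reference scale).
#' @param weight Individual body weight, kg.
#' @return A `pk_parameters` object scaled to `weight` (its `ref_weight`
#'   is set to `weight` so further scaling is a no-op).
#' @export
scale_pk <- function(pk, weight) {
  stopifnot(inherits(pk, "pk_parameters"))
  pk_parameters(
    cl_f = allometric_scale(pk$cl_f, weight, pk$exp_cl, pk$ref_weight),
    v1_f = allometric_scale(pk$v1_f, weight, pk$exp_v, pk$ref_weight),
    q_f = allometric_scale(pk$q_f, weight, pk$exp_cl, pk$ref_weight),
    v2_f = allometric_scale(pk$v2_f, weight, pk$exp_v, pk$ref_weight),
    d1 = pk$d1, ref_weight = weight, exp_cl = pk$exp_cl, exp_v = pk$exp_v
  )
}

#' Dosing regimen
#'
#' A regimen is a tibble of zero-order dose events with columns `start`
#' (days), `amount_mg` and `duration` (days, the zero-order absorption
#' window). An empty regimen (no rows) means no drug.
#'
#' @param start Event start times, days (non-decreasing).
#' @param amount_mg Dose amounts, mg (non-negative).
#' @param duration Zero-order input durations, days. Recycled.
#' @return A tibble of class `regimen`.
#' @examples
#' regimen(start = seq(0, 6.5, by = 0.5), amount_mg = 4000, duration = 0.0625)
#' @export
regimen <- function(start = numeric(), amount_mg = numeric(),
                    duration = 0.0625) {
  n <- max(length(start), length(amount_mg))
  if (n == 0L) {
    return(structure(tibble::tibble(start = numeric(), amount_mg = numeric(),
                                    duration = numeric()),
                     class = c("regimen", "tbl_df", "tbl", "data.frame")))
  }
  start <- rep_len(start, n); amount_mg <- rep_len(amount_mg, n)
  duration <- rep_len(duration, n)
  if (is.unsorted(start)) stop("regimen: `start` must be non-decreasing",
                               call. = FALSE)
  if (any(amount_mg < 0)) stop("regimen: `amount_mg` must be >= 0",
                               call. = FALSE)
  if (any(duration <= 0)) stop("regimen: `duration` must be > 0",
                               call. = FALSE)
  structure(tibble::tibble(start = start, amount_mg = amount_mg,
                           duration = duration),
            class = c("regimen", "tbl_df", "tbl", "data.frame"))
}

# macro constants of the two-compartment disposition model:
# hybrid rate constants (alpha, beta) and bi-exponential coefficients for a
# unit-rate zero-order input into the central compartment
.pk_macro <- function(pk) {
  k10 <- pk$cl_f / pk$v1_f
  k12 <- pk$q_f / pk$v1_f
  k21 <- pk$q_f / pk$v2_f
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(lambda = c(alpha, beta),
       coef = c((alpha - k21) / (alpha - beta), (k21 - beta) / (alpha - beta)),
       v1 = pk$v1_f)
}

# single-event plasma contribution at elapsed times tau >= 0 (vectorised);
# rate in ug/day. tau <= 0 contributes 0.
.plasma_event <- function(macro, rate_ug_day, d1, tau) {
  out <- numeric(length(tau))
  on <- tau > 0
  if (!any(on)) return(out)
  tau <- tau[on]
  t1 <- pmin(tau, d1)
  t2 <- pmax(tau - d1, 0)
  acc <- 0
  for (j in 1:2) {
    lam <- macro$lambda[j]
    acc <- acc + (macro$coef[j] / lam) * (1 - exp(-lam * t1)) * exp(-lam * t2)
  }
  out[on] <- (rate_ug_day / macro$v1) * acc
  out
}

# single-event effect-site contribution; exact piecewise-analytic solution of
# dCe/dt = ke0 (Cp - Ce) for the zero-order-input bi-exponential Cp
.ce_event <- function(macro, rate_ug_day, d1, ke0, tau) {
  out <- numeric(length(tau))
  on <- tau > 0
  if (!any(on)) return(out)
  tau <- tau[on]
  # k/(k - lam) * (exp(-lam u) - exp(-k u)), stable near k == lam
  kern <- function(lam, u) {
    d <- ke0 - lam
    if (abs(d) < 1e-10 * max(ke0, lam)) {
      ke0 * u * exp(-ke0 * u)
    } else {
      ke0 / d * (exp(-lam * u) - exp(-ke0 * u))
    }
  }
  t1 <- pmin(tau, d1)
  t2 <- pmax(tau - d1, 0)
  acc <- 0
  for (j in 1:2) {
    lam <- macro$lambda[j]
    aj <- macro$coef[j] / lam
    # value accrued during the (possibly partial) infusion window
    phase1 <- aj * ((1 - exp(-ke0 * t1)) - kern(lam, t1))
    # infusion-phase value decayed + post-infusion input
    acc <- acc + phase1 * exp(-ke0 * t2) +
      aj * (1 - exp(-lam * d1)) * (tau > d1) * kern(lam, t2)
  }
  out[on] <- (rate_ug_day / macro$v1) * acc
  out
}

#' Plasma concentration under a dosing regimen
#'
#' Closed-form plasma concentration of the two-compartment model with
#' zero-order absorption, by superposition of the bi-exponential single-dose
#' response over all dose events. There is no endogenous production term:
#' the concentration is exogenous drug only and returns to zero after the
#' last dose.
#'
#' @param pk A [pk_parameters()] object, already scaled to the individual
#'   (see [scale_pk()]).
#' @param reg A [regimen()].
#' @param times Evaluation times, days (non-negative).
#' @return Numeric vector of plasma concentrations, micrograms/L.
#' @examples
#' pk <- scale_pk(pk_parameters(), weight = 20.5)
#' reg <- regimen(start = 0, amount_mg = 2000, duration = pk$d1)
#' plasma_concentration(pk, reg, times = c(0.05, 0.5, 1, 2))
#' @export
plasma_concentration <- function(pk, reg, times) {
  stopifnot(inherits(pk, "pk_parameters"))
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("plasma_concentration: `times` must be non-negative", call. = FALSE)
  }
  macro <- .pk_macro(pk)
  conc <- numeric(length(times))
  if (nrow(reg) == 0L) return(conc)
  for (i in seq_len(nrow(reg))) {
    rate <- 1000 * reg$amount_mg[i] / reg$duration[i] # mg -> ug
    conc <- conc + .plasma_event(macro, rate, reg$duration[i],
                                 times - reg$start[i])
  }
  conc
}

#' Effect-site concentration
#'
#' Solves the effect-compartment equation \eqn{dC_e/dt = k_{e0}(C_p - C_e)}
#' with \eqn{C_e(0) = 0} (drug-naive subjects). When `pk` and `reg` are
#' supplied the solution is exact (piecewise-analytic convolution of the
#' closed-form plasma curve with the `ke0` kernel, superposed over dose
#' events). Alternatively a sampled plasma profile may be supplied, in
#' which case the convolution is integrated numerically on the profile's
#' grid (piecewise-linear plasma).
#'
#' @param ke0 Effect-site rate constant, 1/day (> 0).
#' @param times Evaluation times, days.
#' @param pk,reg Individual PK parameters and regimen (analytic route).
#' @param plasma A data frame with columns `time` and `plasma` (numeric
#'   route); must cover `[0, max(times)]`.
#' @return Numeric vector of effect-site concentrations, micrograms/L.
#' @examples
#' pk <- scale_pk(pk_parameters(), weight = 20.5)
#' reg <- regimen(start = seq(0, 83.5, 0.5), amount_mg = 4000)
#' effect_site_concentration(0.0065, times = c(0, 42, 84), pk = pk, reg = reg)
#' @export
effect_site_concentration <- function(ke0, times, pk = NULL, reg = NULL,
                                      plasma = NULL) {
  if (!is.finite(ke0) || ke0 <= 0) {
    stop("effect_site_concentration: `ke0` must be positive", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("effect_site_concentration: `times` must be non-negative",
         call. = FALSE)
  }
  if (!is.null(pk) && !is.null(reg)) {
    macro <- .pk_macro(pk)
    ce <- numeric(length(times))
    if (nrow(reg) == 0L) return(ce)
    for (i in seq_len(nrow(reg))) {
      rate <- 1000 * reg$amount_mg[i] / reg$duration[i]
      ce <- ce + .ce_event(macro, rate, reg$duration[i], ke0,
                           times - reg$start[i])
    }
    return(ce)
  }
  if (is.null(plasma)) {
    stop("effect_site_concentration: supply either `pk` + `reg` or `plasma`",
         call. = FALSE)
  }
  stopifnot(all(c("time", "plasma") %in% names(plasma)))
  tg <- plasma$time
  cp <- plasma$plasma
  if (min(tg) > 0 || max(tg) < max(times)) {
    stop("effect_site_concentration: `plasma` must cover [0, max(times)]",
         call. = FALSE)
  }
  # exact update over each grid interval assuming Cp linear on the interval
  n <- length(tg)
  ce_grid <- numeric(n)
  for (i in 2:n) {
    h <- tg[i] - tg[i - 1]
    if (h <= 0) { ce_grid[i] <- ce_grid[i - 1]; next }
    slope <- (cp[i] - cp[i - 1]) / h
    ek <- exp(-ke0 * h)
    # Ce(t+h) for Cp(s) = cp0 + slope s on the interval
    ce_grid[i] <- ce_grid[i - 1] * ek + cp[i - 1] * (1 - ek) +
      slope * (h - (1 - ek) / ke0)
  }
  stats::approx(tg, ce_grid, xout = times, rule = 2)$y
}

#' Concentration profile on a time grid
#'
#' Convenience wrapper returning plasma and effect-site concentrations
#' together.
#'
#' @inheritParams effect_site_concentration
#' @param pk Individual-scale [pk_parameters()].
#' @param reg A [regimen()].
#' @param times Evaluation times, days.
#' @return A tibble with columns `time`, `plasma`, `effect_site`.
#' @export
concentration_profile <- function(pk, reg, times, ke0) {
  tibble::tibble(
    time = times,
    plasma = plasma_concentration(pk, reg, times),
    effect_site = effect_site_concentration(ke0, times, pk = pk, reg = reg)
  )
}

#' Typical baseline score at a given age
#'
#' Power covariate model of age on the population baseline score:
#' `e0 * (age / age_ref)^beta_age`, normalised at the reference age.
#'
#' @param e0 Population baseline score at `age_ref`.
#' @param age Age, years (> 0; vectorised).
#' @param beta_age Covariate exponent (negative values mean younger
#'   children score higher).
#' @param age_ref Reference age, years.
#' @return Typical baseline score(s).
#' @examples
#' baseline_with_age(48.51, age = 10, beta_age = -0.21)
#' @export
baseline_with_age <- function(e0, age, beta_age, age_ref = 5) {
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("baseline_with_age: `age` must be positive", call. = FALSE)
  }
  e0 * (age / age_ref)^beta_age
}

#' Predicted score of the effect-compartment model
#'
#' Structural score prediction for one individual:
#' `e0_i + kprog_i * t + deff_i * ce`. The baseline term `e0_i` should
#' already include any covariate effect and eta.
#'
#' @param e0_i Individual baseline score.
#' @param kprog_i Individual progression slope, points/day.
#' @param deff_i Individual drug-effect slope, L/microgram.
#' @param ce Effect-site concentration at `t`, micrograms/L.
#' @param t Time, days (>= 0).
#' @return Predicted score (vectorised over any argument).
#' @examples
#' score_model(48.51, 0.015, 0.0022, ce = 0, t = 84)
#' @export
score_model <- function(e0_i, kprog_i, deff_i, ce, t) {
  if (any(t < 0)) stop("score_model: `t` must be >= 0", call. = FALSE)
  e0_i + kprog_i * t + deff_i * ce
}

#' Effect-site equilibration half-life
#'
#' Half-life of effect-compartment equilibration, `ln(2)/ke0`, expressed in
#' weeks. With the default `ke0` of 0.0065/day this is about 15 weeks.
#'
#' @param ke0 Effect-site rate constant, 1/day (> 0).
#' @return Half-life in weeks.
#' @examples
#' equilibration_half_life(0.0065)
#' @export
equilibration_half_life <- function(ke0) {
  if (any(!is.finite(ke0)) || any(ke0 <= 0)) {
    stop("equilibration_half_life: `ke0` must be positive", call. = FALSE)
  }
  log(2) / ke0 / 7
}
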