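#' Sample inter-individual random effects (etas)
#'
#' Draws the four subject-level etas of the score model. All four are
#' jointly normal with mean zero: `eta_ke0` and `eta_deff` are independent,
#' while `eta_e0` and `eta_kprog` share the specified correlation. The
#' `ke0`, `e0` and `deff` etas act multiplicatively (log-normal IIV) and
#' the `kprog` eta additively on the natural scale.
#'
#' @param spec A [random_effect_spec()].
#' @param n Number of subjects (>= 1).
#' @param seed Optional integer seed; draws are reproducible given the seed
#'   and leave the caller's RNG state untouched.
#' @return A tibble with `n` rows and columns `eta_ke0`, `eta_e0`,
#'   `eta_deff`, `eta_kprog`.
#' @examples
#' sample_etas(random_effect_spec(), n = 5, seed = 1)
#' @export
sample_etas <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "random_effect_spec"))
  if (!is.numeric(n) || n < 1) stop("sample_etas: `n` must be >= 1",
                                    call. = FALSE)
  sigma <- eta_covariance(spec)
  act <- which(diag(sigma) > 0)
  draw <- function() {
    z <- matrix(stats::rnorm(4 * n), nrow = n)
    e <- matrix(0, n, 4) # zero-omega components are exactly zero
    if (length(act)) {
      e[, act] <- z[, act, drop = FALSE] %*%
        chol(sigma[act, act, drop = FALSE])
    }
    tibble::tibble(eta_ke0 = e[, 1], eta_e0 = e[, 2], eta_deff = e[, 3],
                   eta_kprog = e[, 4])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Covariance matrix of the eta vector
#'
#' @param spec A [random_effect_spec()].
#' @return 4x4 covariance matrix in the order
#'   (`eta_ke0`, `eta_e0`, `eta_deff`, `eta_kprog`).
#' @export
eta_covariance <- function(spec) {
  stopifnot(inherits(spec, "random_effect_spec"))
  s <- diag(c(spec$omega_ke0, spec$omega_e0, spec$omega_deff,
              spec$omega_kprog)^2)
  cov_ek <- spec$corr_e0_kprog * spec$omega_e0 * spec$omega_kprog
  s[2, 4] <- s[4, 2] <- cov_ek
  dimnames(s) <- rep(list(c("eta_ke0", "eta_e0", "eta_deff", "eta_kprog")), 2)
  # the (e0, kprog) block is PSD iff |corr| <= 1, enforced by the constructor
  s
}

#' Build individual parameters from fixed effects, etas and demographics
#'
#' Combines the population fixed effects with one subject's covariates and
#' etas: `ke0_i = ke0 exp(eta_ke0)`,
#' `e0_i = e0 (age/age_ref)^beta_age exp(eta_e0)`,
#' `deff_i = deff exp(eta_deff)`, `kprog_i = kprog + eta_kprog`; PK
#' parameters are allometrically scaled to the subject's weight.
#'
#' @param params A [model_parameters()] object (`ranef` is not used here).
#' @param etas A one-row data frame (or named list/vector) with `eta_ke0`,
#'   `eta_e0`, `eta_deff`, `eta_kprog`; or a multi-row data frame matched to
#'   `demog` rows.
#' @param demog A data frame with columns `age` (years) and `weight` (kg);
#'   one row per subject.
#' @return A tibble with one row per subject: `ke0_i`, `e0_i`, `deff_i`,
#'   `kprog_i`, `cl_i`, `v1_i`, `q_i`, `v2_i`.
#' @examples
#' demog <- tibble::tibble(age = 5, weight = 70)
#' etas <- tibble::tibble(eta_ke0 = 0, eta_e0 = 0, eta_deff = 0, eta_kprog = 0)
#' individualize(model_parameters(), etas, demog)
#' @export
individualize <- function(params, etas, demog) {
  stopifnot(inherits(params, "model_parameters"))
  etas <- tibble::as_tibble(as.list(etas)[c("eta_ke0", "eta_e0", "eta_deff",
                                            "eta_kprog")])
  demog <- tibble::as_tibble(demog)
  if (!all(c("age", "weight") %in% names(demog))) {
    stop("individualize: `demog` needs `age` and `weight` columns",
         call. = FALSE)
  }
  if (nrow(etas) != nrow(demog)) {
    stop("individualize: `etas` and `demog` must have matching rows",
         call. = FALSE)
  }
  pd <- params$pd; pk <- params$pk
  tibble::tibble(
    ke0_i = pd$ke0 * exp(etas$eta_ke0),
    e0_i = baseline_with_age(pd$e0, demog$age, pd$beta_age, pd$age_ref) *
      exp(etas$eta_e0),
    deff_i = pd$deff * exp(etas$eta_deff),
    kprog_i = pd$kprog + etas$eta_kprog,
    cl_i = allometric_scale(pk$cl_f, demog$weight, pk$exp_cl, pk$ref_weight),
    v1_i = allometric_scale(pk$v1_f, demog$weight, pk$exp_v, pk$ref_weight),
    q_i = allometric_scale(pk$q_f, demog$weight, pk$exp_cl, pk$ref_weight),
    v2_i = allometric_scale(pk$v2_f, demog$weight, pk$exp_v, pk$ref_weight)
  )
}

#' Add additive residual error to predicted scores
#'
#' @param predicted Numeric vector of model-predicted scores.
#' @param sigma_add Residual SD, score points (>= 0).
#' @param seed Optional integer seed (reproducible, RNG-state preserving).
#' @return `predicted + N(0, sigma_add^2)` noise.
#' @export
add_residual <- function(predicted, sigma_add, seed = NULL) {
  if (!is.finite(sigma_add) || sigma_add < 0) {
    stop("add_residual: `sigma_add` must be >= 0", call. = FALSE)
  }
  draw <- function() predicted + stats::rnorm(length(predicted), 0, sigma_add)
  if (sigma_add == 0) return(predicted)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
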