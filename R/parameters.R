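#' Apparent pharmacokinetic parameters for a two-compartment model
#'
#' Constructs the fixed-effect PK parameter set used throughout the package:
#' a two-compartment disposition model with zero-order (constant-rate)
#' absorption of duration `d1` and linear elimination, parameterised in
#' apparent (dose / bioavailability) terms. Parameters are defined at a
#' reference body weight and scaled to individuals by allometry
#' (exponent `exp_cl` for the clearances CL/F and Q/F, `exp_v` for the
#' volumes V1/F and V2/F); see [allometric_scale()].
#'
#' Time is measured in days and concentrations in micrograms per litre
#' everywhere in the package, so clearances are L/day and amounts are mg.
#'
#' @param cl_f Apparent clearance CL/F at the reference weight, L/day.
#' @param v1_f Apparent central volume V1/F, L.
#' @param q_f Apparent inter-compartmental clearance Q/F, L/day.
#' @param v2_f Apparent peripheral volume V2/F, L.
#' @param d1 Duration of the zero-order absorption phase, days. Must be
#'   shorter than the dosing interval.
#' @param ref_weight Reference body weight, kg.
#' @param exp_cl Allometric exponent applied to `cl_f` and `q_f`.
#' @param exp_v Allometric exponent applied to `v1_f` and `v2_f`.
#'
#' @details The default values are placeholders on an adult scale
#'   (reference 70 kg) chosen to be consistent with rapid absorption
#'   (time to peak 0.75--2 h) and a terminal half-life of 7--14 h; they are
#'   **not** estimates from pediatric data. Substitute published adult
#'   population estimates for any analysis in which the absolute exposure
#'   scale matters. Estimation functions in this package hold PK fixed and
#'   all self-consistency checks are invariant to these values.
#'
#' @return An object of class `pk_parameters` (a named list).
#' @examples
#' pk <- pk_parameters()
#' allometric_scale(pk$cl_f, weight = 20.5, exponent = pk$exp_cl,
#'                  ref_weight = pk$ref_weight)
#' @export
pk_parameters <- function(cl_f = 504, v1_f = 28, q_f = 67, v2_f = 40,
                          d1 = 0.0625, ref_weight = 70,
                          exp_cl = 0.75, exp_v = 1.0) {
  x <- list(cl_f = cl_f, v1_f = v1_f, q_f = q_f, v2_f = v2_f, d1 = d1,
            ref_weight = ref_weight, exp_cl = exp_cl, exp_v = exp_v)
  for (nm in c("cl_f", "v1_f", "q_f", "v2_f", "d1", "ref_weight")) {
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L || !is.finite(x[[nm]]) ||
        x[[nm]] <= 0) {
      stop("pk_parameters: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  structure(x, class = "pk_parameters")
}

#' Pharmacodynamic fixed effects for the score model
#'
#' Fixed effects of the effect-compartment score model: the observed
#' adaptive-behavior composite score is
#' \deqn{S(t) = E_0 (age/age_{ref})^{\beta_{age}} + K_{prog} t + D_{eff} C_e(t) + \epsilon,}
#' where \eqn{C_e} is the effect-site concentration governed by
#' \eqn{dC_e/dt = k_{e0} (C_p - C_e)}.
#'
#' @param ke0 Effect-site equilibration rate constant, 1/day.
#' @param e0 Population baseline score at the reference age.
#' @param beta_age Exponent of the power covariate model of age on `e0`
#'   (dimensionless; 0 disables the covariate).
#' @param deff Linear drug-effect slope, score points per (microgram/L) of
#'   effect-site concentration (i.e. L/microgram).
#' @param kprog Natural progression slope of the score, points/day.
#' @param age_ref Reference age for the covariate normalisation, years.
#'
#' @return An object of class `pd_parameters` (a named list).
#' @examples
#' pd <- pd_parameters()
#' equilibration_half_life(pd$ke0) # about 15 weeks
#' @export
pd_parameters <- function(ke0 = 0.0065, e0 = 48.51, beta_age = -0.21,
                          deff = 0.0022, kprog = 0.015, age_ref = 5) {
  if (!is.finite(ke0) || ke0 <= 0) {
    stop("pd_parameters: `ke0` must be positive", call. = FALSE)
  }
  if (!is.finite(e0) || e0 <= 0) {
    stop("pd_parameters: `e0` must be positive", call. = FALSE)
  }
  if (!is.finite(age_ref) || age_ref <= 0) {
    stop("pd_parameters: `age_ref` must be positive", call. = FALSE)
  }
  structure(list(ke0 = ke0, e0 = e0, beta_age = beta_age, deff = deff,
                 kprog = kprog, age_ref = age_ref),
            class = "pd_parameters")
}

#' Inter-individual variability and residual error specification
#'
#' Standard deviations of the subject-level random effects (etas) and the
#' additive residual error. `ke0`, `e0` and `deff` carry log-normal
#' variability (the eta acts on the log scale), while `kprog` has an
#' additive normal eta on the natural scale; the `e0` and `kprog` etas may
#' be correlated.
#'
#' @param omega_ke0,omega_e0,omega_deff SDs of the log-scale etas.
#' @param omega_kprog SD of the additive eta on `kprog`, points/day.
#' @param corr_e0_kprog Correlation between the `e0` and `kprog` etas.
#' @param sigma_add Additive residual SD, score points.
#'
#' @return An object of class `random_effect_spec` (a named list).
#' @export
random_effect_spec <- function(omega_ke0 = 0.21, omega_e0 = 0.2,
                               omega_deff = 1.4, omega_kprog = 0.018,
                               corr_e0_kprog = 0.48, sigma_add = 1.6) {
  sds <- c(omega_ke0, omega_e0, omega_deff, omega_kprog, sigma_add)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("random_effect_spec: SDs must be finite and non-negative",
         call. = FALSE)
  }
  if (!is.finite(corr_e0_kprog) || abs(corr_e0_kprog) > 1) {
    stop("random_effect_spec: `corr_e0_kprog` must lie in [-1, 1]",
         call. = FALSE)
  }
  structure(list(omega_ke0 = omega_ke0, omega_e0 = omega_e0,
                 omega_deff = omega_deff, omega_kprog = omega_kprog,
                 corr_e0_kprog = corr_e0_kprog, sigma_add = sigma_add),
            class = "random_effect_spec")
}

#' Bundle PK, PD and random-effect parameters
#'
#' @param pk A [pk_parameters()] object.
#' @param pd A [pd_parameters()] object.
#' @param ranef A [random_effect_spec()] object.
#' @return An object of class `model_parameters`.
#' @examples
#' params <- model_parameters()
#' params$pd$kprog
#' @export
model_parameters <- function(pk = pk_parameters(), pd = pd_parameters(),
                             ranef = random_effect_spec()) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd, "pd_parameters"),
            inherits(ranef, "random_effect_spec"))
  structure(list(pk = pk, pd = pd, ranef = ranef),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat("PK (apparent, at", x$pk$ref_weight, "kg):",
      sprintf("CL/F %.3g L/day, V1/F %.3g L, Q/F %.3g L/day, V2/F %.3g L, D1 %.3g day",
              x$pk$cl_f, x$pk$v1_f, x$pk$q_f, x$pk$v2_f, x$pk$d1), "\n")
  cat("PD:", sprintf("ke0 %.4g /day, E0 %.4g, beta_age %.3g, Deff %.4g L/ug, Kprog %.4g /day",
                     x$pd$ke0, x$pd$e0, x$pd$beta_age, x$pd$deff, x$pd$kprog), "\n")
  cat("IIV:", sprintf("omega ke0 %.3g, E0 %.3g, Deff %.3g, Kprog %.3g; corr(E0,Kprog) %.3g; sigma %.3g",
                      x$ranef$omega_ke0, x$ranef$omega_e0, x$ranef$omega_deff,
                      x$ranef$omega_kprog, x$ranef$corr_e0_kprog,
                      x$ranef$sigma_add), "\n")
  invisible(x)
}

# flat config keys carry explicit units so that serialized parameter files
# are unambiguous on their own
.param_config_keys <- list(
  pk = c(cl_f = "cl_f_L_per_day", v1_f = "v1_f_L", q_f = "q_f_L_per_day",
         v2_f = "v2_f_L", d1 = "d1_day", ref_weight = "ref_weight_kg",
         exp_cl = "exp_cl", exp_v = "exp_v"),
  pd = c(ke0 = "ke0_per_day", e0 = "e0_score", beta_age = "beta_age",
         deff = "deff_L_per_ug", kprog = "kprog_score_per_day",
         age_ref = "age_ref_years"),
  ranef = c(omega_ke0 = "omega_ke0", omega_e0 = "omega_e0",
            omega_deff = "omega_deff",
            omega_kprog = "omega_kprog_score_per_day",
            corr_e0_kprog = "corr_e0_kprog",
            sigma_add = "sigma_add_score")
)

#' Read and write model parameters as a flat config file
#'
#' Parameters are serialized as a flat YAML (or JSON) mapping whose keys
#' embed the unit (e.g. `cl_f_L_per_day`), grouped under `pk`, `pd` and
#' `random_effects`.
#'
#' @param params A [model_parameters()] object.
#' @param path File path; `.json` is written/read as JSON, anything else as
#'   YAML.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a [model_parameters()] object.
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  blocks <- list(pk = "pk", pd = "pd", random_effects = "ranef")
  out <- lapply(blocks, function(b) {
    keys <- .param_config_keys[[b]]
    stats::setNames(lapply(names(keys), function(f) params[[b]][[f]]),
                    unname(keys))
  })
  out$note <- paste("PK values are documented placeholders on an adult",
                    "scale - substitute published adult estimates")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pull <- function(block, b) {
    keys <- .param_config_keys[[b]]
    missing <- setdiff(unname(keys), names(block))
    if (length(missing)) {
      stop("read_model_config: missing keys: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    stats::setNames(lapply(unname(keys), function(k) as.numeric(block[[k]])),
                    names(keys))
  }
  model_parameters(
    pk = do.call(pk_parameters, pull(raw$pk, "pk")),
    pd = do.call(pd_parameters, pull(raw$pd, "pd")),
    ranef = do.call(random_effect_spec, pull(raw$random_effects, "ranef"))
  )
}
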