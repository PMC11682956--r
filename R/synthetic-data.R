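# Embedded sex-by-age median body weights (kg), ages 2-12, loosely following
# growth-chart medians; interpolated linearly in age. The generator needs
# only the monotone age-weight structure, not LMS-level fidelity.
.growth_table <- function() {
  tibble::tibble(
    age = 2:12,
    male = c(12.5, 14.5, 16.5, 18.5, 21.0, 23.5, 26.5, 29.5, 33.0, 37.0, 41.0),
    female = c(12.0, 14.0, 16.0, 18.0, 20.5, 23.0, 26.0, 29.5, 34.0, 38.0, 42.0)
  )
}

#' Median weight-for-age of the embedded growth table
#'
#' @param age Age(s) in years, within 2--12.
#' @param sex `"male"` or `"female"` (recycled).
#' @return Median body weight(s), kg.
#' @export
median_weight_for_age <- function(age, sex = "male") {
  gt <- .growth_table()
  sex <- rep_len(sex, length(age))
  if (!all(sex %in% c("male", "female"))) {
    stop("median_weight_for_age: `sex` must be 'male' or 'female'",
         call. = FALSE)
  }
  m <- stats::approx(gt$age, gt$male, xout = age, rule = 2)$y
  f <- stats::approx(gt$age, gt$female, xout = age, rule = 2)$y
  ifelse(sex == "male", m, f)
}

#' Generate a virtual pediatric population
#'
#' Draws demographics with the correlation structure the trial simulator
#' needs: ages uniform on `age_range`, sex with the configured male
#' fraction, and weight log-normal around a sex-specific median
#' weight-for-age (embedded growth table), truncated to
#' `weight_limits`. Baseline total serine is drawn log-normally around the
#' cohort median as an optional covariate.
#'
#' @param n Number of subjects.
#' @param age_range Age range in years, within `[2, 12]`.
#' @param sex_male_fraction Probability a subject is male (default 0.828,
#'   the emulated cohort's proportion).
#' @param weight_cv Lognormal coefficient of variation of weight around the
#'   median weight-for-age (default 0.15).
#' @param weight_limits Truncation envelope for weight, kg.
#' @param serine_median,serine_sdlog Median (micromol/L) and log-SD of
#'   baseline total serine.
#' @param seed Optional integer seed.
#' @return A tibble with columns `id`, `age`, `weight`, `sex`,
#'   `baseline_serine`.
#' @examples
#' generate_population(5, seed = 1)
#' @export
generate_population <- function(n, age_range = c(2, 11),
                                sex_male_fraction = 0.828,
                                weight_cv = 0.15,
                                weight_limits = c(10, 60),
                                serine_median = 128, serine_sdlog = 0.5,
                                seed = NULL) {
  if (!is.numeric(n) || n < 1) {
    stop("generate_population: `n` must be >= 1", call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] >= age_range[2] ||
      age_range[1] < 2 || age_range[2] > 12) {
    stop("generate_population: `age_range` must be an increasing pair within [2, 12]",
         call. = FALSE)
  }
  draw <- function() {
    age <- stats::runif(n, age_range[1], age_range[2])
    sex <- ifelse(stats::runif(n) < sex_male_fraction, "male", "female")
    med <- median_weight_for_age(age, sex)
    sdlog <- sqrt(log(1 + weight_cv^2))
    weight <- med * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    weight <- pmin(pmax(weight, weight_limits[1]), weight_limits[2])
    serine <- serine_median * exp(stats::rnorm(n, 0, serine_sdlog))
    tibble::tibble(id = seq_len(n), age = age, weight = weight, sex = sex,
                   baseline_serine = serine)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Randomise subjects to trial arms
#'
#' @param demog Demographics tibble (see [generate_population()]).
#' @param design A [trial_design()]; its `arms` and `arm_ratio` define the
#'   allocation.
#' @param seed Optional integer seed.
#' @return `demog` with an `arm` column added (permuted-block-free simple
#'   allocation honouring the ratio as closely as `n` allows).
#' @export
assign_arms <- function(demog, design, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  n <- nrow(demog)
  w <- design$arm_ratio / sum(design$arm_ratio)
  counts <- floor(n * w)
  rem <- n - sum(counts)
  if (rem > 0) counts[order(n * w - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(n * w - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  pool <- rep(design$arms, counts)
  perm <- function() sample(pool)
  demog$arm <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())
  demog
}

#' Simulate a complete synthetic trial dataset
#'
#' Full generative pass for one virtual trial: demographics (generated or
#' supplied), arm allocation, weight-tiered regimens, correlated etas,
#' individual parameters, effect-site concentrations at the visit days,
#' structural scores and additive residual error. Baseline is observed at
#' day 0 before the first dose (effect-site concentration zero).
#'
#' @param design A [trial_design()].
#' @param params A [model_parameters()].
#' @param n Number of subjects (ignored when `demog` is supplied).
#' @param demog Optional demographics tibble; must contain `id`, `age`,
#'   `weight`, `sex` and optionally `arm` (allocated when absent).
#' @param seed Integer seed; the whole dataset is reproducible given it.
#' @return A `trial_dataset`: a list of tibbles `demographics` (with arm),
#'   `dosing` (`id`, `start`, `amount_mg`, `duration`) and `observations`
#'   (`id`, `time`, `score`, `missing`), carrying the design and seed as
#'   attributes.
#' @examples
#' ds <- simulate_dataset(phase2_design(), model_parameters(), n = 12, seed = 1)
#' ds$observations
#' @export
simulate_dataset <- function(design, params, n = 145, demog = NULL,
                             seed = NULL) {
  stopifnot(inherits(design, "trial_design"),
            inherits(params, "model_parameters"))
  run <- function() {
    dm <- if (is.null(demog)) {
      generate_population(n)
    } else tibble::as_tibble(demog)
    if (!"arm" %in% names(dm)) dm <- assign_arms(dm, design)
    nsub <- nrow(dm)
    etas <- sample_etas(params$ranef, nsub)
    ind <- individualize(params, etas, dm)
    visits <- design$visit_days
    dose_rows <- vector("list", nsub)
    obs_rows <- vector("list", nsub)
    for (i in seq_len(nsub)) {
      reg <- build_regimen(dm[i, ], design, d1 = params$pk$d1)
      pk_i <- pk_parameters(cl_f = ind$cl_i[i], v1_f = ind$v1_i[i],
                            q_f = ind$q_i[i], v2_f = ind$v2_i[i],
                            d1 = params$pk$d1, ref_weight = dm$weight[i],
                            exp_cl = params$pk$exp_cl,
                            exp_v = params$pk$exp_v)
      ce <- if (nrow(reg) > 0) {
        effect_site_concentration(ind$ke0_i[i], visits, pk = pk_i, reg = reg)
      } else rep(0, length(visits))
      pred <- score_model(ind$e0_i[i], ind$kprog_i[i], ind$deff_i[i],
                          ce = ce, t = visits)
      miss <- c(FALSE, stats::runif(length(visits) - 1) < design$dropout_prob)
      dose_rows[[i]] <- dplyr::mutate(reg, id = dm$id[i], .before = 1)
      obs_rows[[i]] <- tibble::tibble(id = dm$id[i], time = visits,
                                      score = pred, missing = miss)
    }
    obs <- dplyr::bind_rows(obs_rows)
    obs$score <- add_residual(obs$score, params$ranef$sigma_add)
    obs$score[obs$missing] <- NA_real_
    structure(list(demographics = dm,
                   dosing = dplyr::bind_rows(dose_rows),
                   observations = obs),
              class = "trial_dataset", design = design, seed = seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.trial_dataset <- function(x, ...) {
  nobs <- sum(!x$observations$missing)
  cat("<trial_dataset>", nrow(x$demographics), "subjects,",
      nobs, "observed scores,", nrow(x$dosing), "dose events\n")
  print(utils::head(tibble::as_tibble(x$demographics), 4))
  invisible(x)
}
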