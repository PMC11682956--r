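#' Per-subject score change between two visits
#'
#' Difference of the observed (residual-included) scores between two visit
#' days, by default week 12 versus baseline. Subjects missing either visit
#' are excluded and listed in the `excluded` attribute.
#'
#' @param dataset A `trial_dataset` (or its `observations` tibble joined
#'   with demographics columns).
#' @param from_day,to_day Visit days to difference.
#' @return A tibble `id`, `arm` (when available), `delta`; excluded subject
#'   ids in `attr(, "excluded")`.
#' @examples
#' ds <- simulate_dataset(phase2_design(), model_parameters(), n = 10, seed = 1)
#' delta_score(ds)
#' @export
delta_score <- function(dataset, from_day = 0, to_day = 84) {
  obs <- if (inherits(dataset, "trial_dataset")) {
    dplyr::left_join(dataset$observations,
                     dplyr::select(dataset$demographics, "id",
                                   dplyr::any_of("arm")),
                     by = "id")
  } else tibble::as_tibble(dataset)
  ok <- !obs$missing & !is.na(obs$score)
  a <- obs[ok & obs$time == from_day, ]
  b <- obs[ok & obs$time == to_day, ]
  out <- dplyr::inner_join(
    dplyr::select(a, "id", dplyr::any_of("arm"), score_from = "score"),
    dplyr::select(b, "id", score_to = "score"), by = "id")
  excluded <- setdiff(unique(obs$id), out$id)
  if (length(excluded)) {
    message("delta_score: excluded ", length(excluded),
            " subject(s) missing a visit")
  }
  res <- dplyr::select(
    dplyr::mutate(out, delta = .data$score_to - .data$score_from),
    "id", dplyr::any_of("arm"), "delta")
  attr(res, "excluded") <- excluded
  res
}

#' Target attainment
#'
#' Percentage of subjects whose score change strictly exceeds the target
#' (default: more than 2 points).
#'
#' @param deltas Numeric vector of score changes (or a tibble from
#'   [delta_score()]).
#' @param threshold Attainment threshold; strict `>` is used.
#' @return Percentage in `[0, 100]`.
#' @examples
#' target_attainment(c(1, 2, 3)) # 33.3: the boundary value does not count
#' @export
target_attainment <- function(deltas, threshold = 2) {
  if (is.data.frame(deltas)) deltas <- deltas$delta
  if (!length(deltas)) stop("target_attainment: empty `deltas`",
                            call. = FALSE)
  100 * mean(deltas > threshold)
}

#' Dose intensity range implied by a weight band
#'
#' Daily mg/kg range of a fixed BID gram dose over a weight interval,
#' rounded to integer mg/kg/day.
#'
#' @param dose_g_bid Dose per administration, grams (given twice daily).
#' @param weight_low,weight_high Band bounds, kg.
#' @return Named numeric `c(min, max)` mg/kg/day.
#' @examples
#' mgkg_range(2, 10, 13) # 308-400 mg/kg/day
#' @export
mgkg_range <- function(dose_g_bid, weight_low, weight_high) {
  if (any(c(weight_low, weight_high) <= 0)) {
    stop("mgkg_range: weights must be positive", call. = FALSE)
  }
  c(min = round(2000 * dose_g_bid / weight_high),
    max = round(2000 * dose_g_bid / weight_low))
}

# simulate one cohort for `days` of BID dosing at dose_mg per administration
# (0 = placebo) and return observed deltas over [0, days]
.simulate_band_cohort <- function(demog, dose_mg, params, days = 84,
                                  titration_days = 0) {
  n <- nrow(demog)
  etas <- sample_etas(params$ranef, n)
  ind <- individualize(params, etas, demog)
  delta <- numeric(n)
  for (i in seq_len(n)) {
    ce_end <- 0
    if (dose_mg[i] > 0) {
      t_tit <- if (titration_days > 0) seq(0, titration_days - 0.25, 0.5) else numeric()
      t_full <- seq(titration_days, days - 0.25, 0.5)
      reg <- regimen(start = c(t_tit, t_full),
                     amount_mg = c(rep(dose_mg[i] / 2, length(t_tit)),
                                   rep(dose_mg[i], length(t_full))),
                     duration = params$pk$d1)
      pk_i <- pk_parameters(cl_f = ind$cl_i[i], v1_f = ind$v1_i[i],
                            q_f = ind$q_i[i], v2_f = ind$v2_i[i],
                            d1 = params$pk$d1, ref_weight = demog$weight[i])
      ce_end <- effect_site_concentration(ind$ke0_i[i], days, pk = pk_i,
                                          reg = reg)
    }
    s0 <- score_model(ind$e0_i[i], ind$kprog_i[i], ind$deff_i[i], 0, 0)
    s1 <- score_model(ind$e0_i[i], ind$kprog_i[i], ind$deff_i[i], ce_end,
                      days)
    delta[i] <- (s1 - s0)
  }
  delta + stats::rnorm(n, 0, params$ranef$sigma_add * sqrt(2))
}

#' Simulate weight-tiered dose scenarios
#'
#' Phase-III dose-scenario engine: for each weight band, simulates a
#' virtual cohort dosed at the band's BID dose for 12 weeks (plus a matched
#' placebo cohort on the same subjects) and summarises the week-12 score
#' change from baseline by its 5/50/95 percentiles and the target
#' attainment (change > 2 points). Observed deltas include residual error
#' on both visits. Optionally the population fixed effects are themselves
#' redrawn per replicate from an approximate sampling distribution
#' (normal on the transformed scale with the supplied relative standard
#' errors), propagating parameter uncertainty into the percentile bands.
#'
#' @param band_table Weight-band dose table ([weight_bands_phase3()] by
#'   default). The `dose_g` column may be overridden via `dose_levels`.
#' @param params A [model_parameters()].
#' @param n_per_band Virtual subjects per band.
#' @param dose_levels Optional vector recycled over bands replacing the
#'   table's doses (grams BID), e.g. to sweep 2--14 g.
#' @param treatment_days Treatment duration, days.
#' @param include_uncertainty Draw fixed effects per band replicate from
#'   their uncertainty distribution.
#' @param rse_pct Named relative standard errors (percent) used when
#'   `include_uncertainty = TRUE`; defaults to moderate values for
#'   (`ke0`, `e0`, `beta_age`, `deff`, `kprog`).
#' @param seed Integer seed.
#' @return A `simulation_summary` tibble: one row per band with treated and
#'   placebo percentiles, attainments and the band's mg/kg/day range.
#' @examples
#' \donttest{
#' run_dose_scenarios(weight_bands_phase3(), model_parameters(),
#'                    n_per_band = 50, seed = 1)
#' }
#' @export
run_dose_scenarios <- function(band_table = weight_bands_phase3(),
                               params = model_parameters(),
                               n_per_band = 200, dose_levels = NULL,
                               treatment_days = 84,
                               include_uncertainty = FALSE,
                               rse_pct = c(ke0 = 7.92, e0 = 1.66,
                                           beta_age = 18.4, deff = 37.5,
                                           kprog = 12.0),
                               seed = 1) {
  if (!is.null(dose_levels)) {
    band_table$dose_g <- rep_len(dose_levels, nrow(band_table))
  }
  run_band <- function(b) {
    bnd <- band_table[b, ]
    demog <- .band_population(n_per_band, bnd)
    p_use <- if (include_uncertainty) {
      .draw_uncertain_params(params, rse_pct)
    } else params
    treated <- .simulate_band_cohort(demog, rep(1000 * bnd$dose_g,
                                                n_per_band),
                                     p_use, days = treatment_days)
    placebo <- .simulate_band_cohort(demog, rep(0, n_per_band), p_use,
                                     days = treatment_days)
    # the printed band labels are integer-kg (e.g. 10-13 for [10, 14)), and
    # the published mg/kg/day ranges are computed on those labels; the top
    # band is capped at its lower bound (the maximum intensity)
    rng <- mgkg_range(bnd$dose_g, bnd$lower,
                      if (is.finite(bnd$upper)) bnd$upper - 1 else
                        bnd$lower)
    tibble::tibble(
      band = bnd$band, dose_g_bid = bnd$dose_g,
      mgkg_min = rng[["min"]], mgkg_max = rng[["max"]],
      p5 = stats::quantile(treated, 0.05),
      p50 = stats::quantile(treated, 0.5),
      p95 = stats::quantile(treated, 0.95),
      attainment = target_attainment(treated),
      placebo_p5 = stats::quantile(placebo, 0.05),
      placebo_p50 = stats::quantile(placebo, 0.5),
      placebo_p95 = stats::quantile(placebo, 0.95),
      placebo_attainment = target_attainment(placebo),
      n = n_per_band)
  }
  out <- withr::with_seed(seed, dplyr::bind_rows(
    lapply(seq_len(nrow(band_table)), run_band)))
  structure(out, class = c("simulation_summary", class(out)))
}

# virtual subjects whose weights fall inside one band: resample the
# population generator conditionally on the band
.band_population <- function(n, band) {
  got <- tibble::tibble()
  tries <- 0
  while (nrow(got) < n && tries < 60) {
    cand <- generate_population(max(4 * n, 200), age_range = c(2, 12))
    cand <- cand[cand$weight >= band$lower & cand$weight < band$upper, ]
    got <- dplyr::bind_rows(got, cand)
    tries <- tries + 1
  }
  if (nrow(got) < n) {
    # extreme bands may be sparse in the growth envelope: top up with
    # uniform weights inside the band
    extra <- generate_population(n, age_range = c(2, 12))
    hi <- if (is.finite(band$upper)) band$upper else band$lower + 10
    extra$weight <- stats::runif(n, band$lower, hi)
    got <- dplyr::bind_rows(got, extra)
  }
  got <- got[seq_len(n), ]
  got$id <- seq_len(n)
  got
}

# fixed-effect uncertainty layer: normal on the transformed scale with
# SD = RSE/100 (log-scale parameters) or RSE/100 * |estimate| (identity)
.draw_uncertain_params <- function(params, rse_pct) {
  pd <- params$pd
  z <- stats::rnorm(5)
  pd2 <- pd_parameters(
    ke0 = pd$ke0 * exp(z[1] * rse_pct[["ke0"]] / 100),
    e0 = pd$e0 * exp(z[2] * rse_pct[["e0"]] / 100),
    beta_age = pd$beta_age + z[3] * abs(pd$beta_age) * rse_pct[["beta_age"]] / 100,
    deff = pd$deff * exp(z[4] * rse_pct[["deff"]] / 100),
    kprog = pd$kprog + z[5] * abs(pd$kprog) * rse_pct[["kprog"]] / 100,
    age_ref = pd$age_ref)
  model_parameters(pk = params$pk, pd = pd2, ranef = params$ranef)
}

#' Compare a fixed weight-band dose with a mg/kg dose
#'
#' Doses the same virtual subjects both ways -- the band's fixed BID gram
#' dose and an exact per-kg BID dose -- with identical etas and residuals,
#' and summarises the paired difference of the week-12 score changes.
#'
#' @param band_table Weight-band dose table.
#' @param mgkg_bid mg/kg per administration of the weight-based comparator
#'   (default 200 mg/kg BID).
#' @param params A [model_parameters()].
#' @param n_per_band Subjects per band.
#' @param treatment_days Treatment duration, days.
#' @param population Optional demographics tibble used for every band
#'   instead of drawing band-conditional virtual subjects.
#' @param seed Integer seed.
#' @return A tibble per band: median delta under each regimen, the median
#'   and IQR of the paired difference.
#' @export
compare_fixed_vs_mgkg <- function(band_table = weight_bands_phase3(),
                                  mgkg_bid = 200,
                                  params = model_parameters(),
                                  n_per_band = 200, treatment_days = 84,
                                  population = NULL, seed = 1) {
  run_band <- function(b) {
    bnd <- band_table[b, ]
    demog <- population %||% .band_population(n_per_band, bnd)
    n_per_band <- nrow(demog)
    etas <- sample_etas(params$ranef, n_per_band)
    ind <- individualize(params, etas, demog)
    eps <- stats::rnorm(n_per_band, 0, params$ranef$sigma_add * sqrt(2))
    one <- function(dose_mg) {
      vapply(seq_len(n_per_band), function(i) {
        reg <- regimen(start = seq(0, treatment_days - 0.25, 0.5),
                       amount_mg = dose_mg[i], duration = params$pk$d1)
        pk_i <- pk_parameters(cl_f = ind$cl_i[i], v1_f = ind$v1_i[i],
                              q_f = ind$q_i[i], v2_f = ind$v2_i[i],
                              d1 = params$pk$d1,
                              ref_weight = demog$weight[i])
        ce <- effect_site_concentration(ind$ke0_i[i], treatment_days,
                                        pk = pk_i, reg = reg)
        ind$kprog_i[i] * treatment_days + ind$deff_i[i] * ce
      }, numeric(1)) + eps
    }
    d_fixed <- one(rep(1000 * bnd$dose_g, n_per_band))
    d_mgkg <- one(mgkg_bid * demog$weight)
    diff <- d_fixed - d_mgkg
    tibble::tibble(band = bnd$band, dose_g_bid = bnd$dose_g,
                   median_fixed = stats::median(d_fixed),
                   median_mgkg = stats::median(d_mgkg),
                   median_diff = stats::median(diff),
                   iqr_fixed = stats::IQR(d_fixed),
                   n = n_per_band)
  }
  withr::with_seed(seed, dplyr::bind_rows(
    lapply(seq_len(nrow(band_table)), run_band)))
}

#' Covariate forest ratios for clearance and baseline score
#'
#' Bins a virtual population by weight and age and reports, per bin, the
#' median (with percentile interval) of the model-predicted individual
#' apparent clearance and baseline score relative to a reference bin. The
#' clearance ratio is driven by allometry (weight^0.75), the baseline ratio
#' by the age power function.
#'
#' @param population Demographics tibble (e.g. [generate_population()]).
#' @param params A [model_parameters()].
#' @param weight_breaks,age_breaks Bin edges (left-closed).
#' @param reference Which bin is the reference: `"last"` (heaviest/oldest,
#'   default) or `"first"`.
#' @param include_iiv Draw etas (`TRUE`) or use typical values.
#' @param ci Interval coverage.
#' @param seed Integer seed.
#' @return A `forest_summary` tibble: `covariate`, `bin`, ratios of CL and
#'   E0 with interval bounds; the reference bin has ratio exactly 1.
#' @export
forest_ratios <- function(population, params = model_parameters(),
                          weight_breaks = c(10, 14, 21, 35, 50, Inf),
                          age_breaks = c(2, 6, 10, 12.001),
                          reference = c("last", "first"),
                          include_iiv = TRUE, ci = 0.95, seed = 1) {
  reference <- match.arg(reference)
  n <- nrow(population)
  etas <- if (include_iiv) {
    sample_etas(params$ranef, n, seed = seed)
  } else {
    tibble::tibble(eta_ke0 = rep(0, n), eta_e0 = 0, eta_deff = 0,
                   eta_kprog = 0)
  }
  ind <- individualize(params, etas, population)
  alpha <- (1 - ci) / 2
  summarise_bins <- function(values, breaks, by, covariate) {
    bin <- cut(by, breaks, right = FALSE, include.lowest = TRUE)
    keep <- !is.na(bin)
    med <- tapply(values[keep], bin[keep], stats::median)
    lo <- tapply(values[keep], bin[keep], stats::quantile, probs = alpha)
    hi <- tapply(values[keep], bin[keep], stats::quantile, probs = 1 - alpha)
    present <- which(!is.na(med))
    ref_idx <- if (reference == "last") max(present) else min(present)
    tibble::tibble(covariate = covariate, bin = names(med)[present],
                   ratio = unname(med[present] / med[ref_idx]),
                   lo = unname(lo[present] / med[ref_idx]),
                   hi = unname(hi[present] / med[ref_idx]),
                   reference = present == ref_idx)
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(summarise_bins(ind$cl_i, weight_breaks,
                                 population$weight, "weight"),
                  quantity = "CL/F"),
    dplyr::mutate(summarise_bins(ind$e0_i, age_breaks, population$age,
                                 "age"),
                  quantity = "E0"),
    dplyr::mutate(summarise_bins(ind$cl_i, age_breaks, population$age,
                                 "age"),
                  quantity = "CL/F"),
    dplyr::mutate(summarise_bins(ind$e0_i, weight_breaks,
                                 population$weight, "weight"),
                  quantity = "E0")
  )
  structure(out, class = c("forest_summary", class(out)))
}

#' Plot a dose-scenario summary
#'
#' @param object A `simulation_summary` from [run_dose_scenarios()].
#' @param ... Unused.
#' @return A ggplot of week-12 score-change percentiles per band, treated
#'   versus placebo.
#' @export
autoplot.simulation_summary <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::transmute(object, band = .data$band, arm = "treated",
                     p5 = .data$p5, p50 = .data$p50, p95 = .data$p95),
    dplyr::transmute(object, band = .data$band, arm = "placebo",
                     p5 = .data$placebo_p5, p50 = .data$placebo_p50,
                     p95 = .data$placebo_p95))
  df$band <- factor(df$band, levels = object$band)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$p50,
                                   colour = .data$arm)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$p5,
                                          ymax = .data$p95),
                             position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_hline(yintercept = 2, linetype = 2) +
    ggplot2::labs(x = "Weight band", y = "Score change at week 12",
                  colour = NULL,
                  title = "Weight-tiered dose scenarios (5/50/95 percentiles)")
}

#' Plot covariate forest ratios
#'
#' @param object A `forest_summary` from [forest_ratios()].
#' @param ... Unused.
#' @return A ggplot forest plot of CL/F and E0 ratios per covariate bin.
#' @export
autoplot.forest_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio, y = .data$bin)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi),
                             colour = "steelblue") +
    ggplot2::facet_grid(covariate ~ quantity, scales = "free_y") +
    ggplot2::labs(x = "Ratio vs reference bin", y = NULL)
}
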