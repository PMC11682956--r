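#' Weight-band dose tables
#'
#' Weight-tiered twice-daily (BID) dose tables. Bands are half-open
#' intervals `[lower, upper)` at the printed lower bounds, the top band
#' being open-ended; e.g. in the phase-III table a 13.6 kg child falls in
#' the 10--13 kg band because 13.6 < 14.
#'
#' `weight_bands_phase3()` is the proposed phase-III table
#' (2/4/6/10/14 g BID for 10--13, 14--20, 21--34, 35--49, >50 kg);
#' `weight_bands_phase2()` is the phase-II trial table
#' (2/4/7/10/14 g BID for 10--14, 15--24, 25--37, 38--51, >=52 kg).
#'
#' @return A tibble with columns `band` (label), `lower`, `upper` (kg;
#'   `upper` is exclusive, `Inf` for the top band) and `dose_g` (grams per
#'   administration, BID).
#' @examples
#' weight_bands_phase3()
#' @export
weight_bands_phase3 <- function() {
  tibble::tibble(
    band = c("10-13 kg", "14-20 kg", "21-34 kg", "35-49 kg", ">=50 kg"),
    lower = c(10, 14, 21, 35, 50),
    upper = c(14, 21, 35, 50, Inf),
    dose_g = c(2, 4, 6, 10, 14)
  )
}

#' @rdname weight_bands_phase3
#' @export
weight_bands_phase2 <- function() {
  tibble::tibble(
    band = c("10-14 kg", "15-24 kg", "25-37 kg", "38-51 kg", ">=52 kg"),
    lower = c(10, 15, 25, 38, 52),
    upper = c(15, 25, 38, 52, Inf),
    dose_g = c(2, 4, 7, 10, 14)
  )
}

#' Look up the weight-band dose for a body weight
#'
#' @param weight Body weight(s), kg.
#' @param band_table A weight-band table (see [weight_bands_phase3()]).
#' @return Dose per administration in grams (BID).
#' @examples
#' assign_weight_band_dose(20.5, weight_bands_phase3()) # 4 g BID
#' @export
assign_weight_band_dose <- function(weight, band_table = weight_bands_phase3()) {
  stopifnot(all(c("lower", "upper", "dose_g") %in% names(band_table)))
  idx <- vapply(weight, function(w) {
    hit <- which(w >= band_table$lower & w < band_table$upper)
    if (length(hit) != 1L) {
      stop("assign_weight_band_dose: weight ", w,
           " kg is outside the band table", call. = FALSE)
    }
    hit
  }, integer(1))
  band_table$dose_g[idx]
}

#' Trial design
#'
#' Describes the three-arm pediatric trial emulated by the synthetic-data
#' generator: weight-tiered BID dosing, a titration period at half dose in
#' the high arm, half dose throughout in the low arm, placebo crossover to
#' high dose at week 12, treatment to week 24 and follow-up at week 36.
#'
#' @param band_table Weight-band dose table ([weight_bands_phase2()] by
#'   default, matching the emulated trial).
#' @param arms Character vector of arm names.
#' @param arm_ratio Randomisation ratio, recycled against `arms`.
#' @param visit_days Score observation days.
#' @param titration_days Length of the half-dose titration period, days.
#' @param crossover_day Day the placebo arm starts active treatment.
#' @param treatment_end Last dosing day (exclusive), days.
#' @param dose_interval Dosing interval, days (0.5 = BID).
#' @param dropout_prob Probability that a post-baseline visit is missing at
#'   random (default 0).
#' @return An object of class `trial_design`.
#' @examples
#' phase2_design()
#' @export
trial_design <- function(band_table = weight_bands_phase2(),
                         arms = c("placebo", "low", "high"),
                         arm_ratio = 1,
                         visit_days = c(0, 84, 168, 252),
                         titration_days = 14,
                         crossover_day = 84,
                         treatment_end = 168,
                         dose_interval = 0.5,
                         dropout_prob = 0) {
  if (is.unsorted(visit_days)) {
    stop("trial_design: `visit_days` must be sorted", call. = FALSE)
  }
  # bands must partition [min(lower), Inf) without gaps or overlaps
  bt <- band_table[order(band_table$lower), ]
  if (any(bt$upper[-nrow(bt)] != bt$lower[-1]) || !is.infinite(bt$upper[nrow(bt)])) {
    stop("trial_design: weight bands must partition the range without gaps",
         call. = FALSE)
  }
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop("trial_design: `dropout_prob` must be in [0, 1)", call. = FALSE)
  }
  structure(list(band_table = band_table, arms = arms,
                 arm_ratio = rep_len(arm_ratio, length(arms)),
                 visit_days = visit_days, titration_days = titration_days,
                 crossover_day = crossover_day, treatment_end = treatment_end,
                 dose_interval = dose_interval, dropout_prob = dropout_prob),
            class = "trial_design")
}

#' @rdname trial_design
#' @export
phase2_design <- function(dropout_prob = 0) {
  trial_design(band_table = weight_bands_phase2(),
               dropout_prob = dropout_prob)
}

#' Build a subject's dosing regimen from the trial design
#'
#' BID zero-order dose events per the arm rules: the high arm receives half
#' the band dose during titration then the full band dose until treatment
#' end; the low arm half the band dose throughout; the placebo arm no drug
#' until the crossover day, then titration plus the full dose until
#' treatment end. No dosing occurs at or after `treatment_end`.
#'
#' @param subject A one-row data frame (or named list) with at least
#'   `weight` (kg) and `arm`.
#' @param design A [trial_design()].
#' @param d1 Zero-order absorption duration attached to each event, days.
#' @return A [regimen()] tibble (possibly with zero rows).
#' @examples
#' build_regimen(list(weight = 25, arm = "high"), phase2_design())
#' @export
build_regimen <- function(subject, design, d1 = 0.0625) {
  subject <- as.list(subject)
  stopifnot(inherits(design, "trial_design"))
  dose_mg <- 1000 * assign_weight_band_dose(subject$weight, design$band_table)
  arm <- as.character(subject$arm)
  step <- design$dose_interval
  grid <- function(from, to) {
    if (to <= from) numeric() else seq(from, to - step / 2, by = step)
  }
  end <- design$treatment_end
  if (arm == "high") {
    t_tit <- grid(0, min(design$titration_days, end))
    t_full <- grid(min(design$titration_days, end), end)
    start <- c(t_tit, t_full)
    amt <- c(rep(dose_mg / 2, length(t_tit)), rep(dose_mg, length(t_full)))
  } else if (arm == "low") {
    start <- grid(0, end)
    amt <- rep(dose_mg / 2, length(start))
  } else if (arm == "placebo") {
    from <- design$crossover_day
    t_tit <- grid(from, min(from + design$titration_days, end))
    t_full <- grid(min(from + design$titration_days, end), end)
    start <- c(t_tit, t_full)
    amt <- c(rep(dose_mg / 2, length(t_tit)), rep(dose_mg, length(t_full)))
  } else {
    stop("build_regimen: unknown arm `", arm, "`", call. = FALSE)
  }
  regimen(start = start, amount_mg = amt, duration = d1)
}

#' Read and write a trial design as a config file
#'
#' @param design A [trial_design()].
#' @param path YAML file path.
#' @return `write_design_config()` returns `path` invisibly;
#'   `read_design_config()` a [trial_design()].
#' @export
write_design_config <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  out <- unclass(design)
  out$band_table <- as.list(as.data.frame(design$band_table))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bt <- tibble::as_tibble(raw$band_table)
  bt$upper <- as.numeric(bt$upper) # YAML may read Inf as string ".inf"
  trial_design(band_table = bt, arms = raw$arms, arm_ratio = raw$arm_ratio,
               visit_days = raw$visit_days,
               titration_days = raw$titration_days,
               crossover_day = raw$crossover_day,
               treatment_end = raw$treatment_end,
               dose_interval = raw$dose_interval,
               dropout_prob = raw$dropout_prob)
}
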