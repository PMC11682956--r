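#' Write a trial dataset as a long-format CSV
#'
#' Serialises a `trial_dataset` (see [simulate_dataset()]) into a single
#' long-format, NONMEM-dialect-compatible CSV with columns `ID`, `TIME`
#' (days), `AMT` (mg; 0 on observation rows), `DUR` (days; absorption
#' duration, 0 on observation rows), `DV` (score; empty on dose rows and
#' missing visits), `MDV`, `AGE`, `WT`, `SEX`, `ARM`, `BSER` (baseline
#' serine, micromol/L; empty when absent). Missing `DV` is encoded as an
#' empty string with `MDV = 1`. A `#`-prefixed metadata header records the
#' package version, seed and a config hash.
#'
#' @param dataset A `trial_dataset`.
#' @param path Output CSV path.
#' @param seed Seed to record in the metadata header (defaults to the
#'   dataset's own seed attribute).
#' @return `path`, invisibly.
#' @export
write_trial_dataset <- function(dataset, path, seed = attr(dataset, "seed")) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dm <- dataset$demographics
  if (!"baseline_serine" %in% names(dm)) dm$baseline_serine <- NA_real_
  dose <- dplyr::transmute(dataset$dosing, ID = .data$id, TIME = .data$start,
                           AMT = .data$amount_mg, DUR = .data$duration,
                           DV = NA_real_, MDV = 1L)
  obs <- dplyr::transmute(dataset$observations, ID = .data$id,
                          TIME = .data$time, AMT = 0, DUR = 0,
                          DV = .data$score,
                          MDV = as.integer(.data$missing))
  long <- dplyr::bind_rows(dose, obs)
  long <- dplyr::left_join(
    long,
    dplyr::transmute(dm, ID = .data$id, AGE = .data$age, WT = .data$weight,
                     SEX = .data$sex, ARM = as.character(.data$arm),
                     BSER = .data$baseline_serine),
    by = "ID"
  )
  long <- dplyr::arrange(long, .data$ID, .data$TIME, dplyr::desc(.data$AMT))
  meta <- c(
    sprintf("# astpkpd version: %s",
            as.character(utils::packageVersion("astpkpd"))),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed)),
    sprintf("# config_hash: %s", .config_hash(attr(dataset, "design")))
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  num <- function(x) ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  header <- c("ID", "TIME", "AMT", "DUR", "DV", "MDV", "AGE", "WT", "SEX",
              "ARM", "BSER")
  writeLines(paste(header, collapse = ","), con)
  body <- paste(long$ID, num(long$TIME), num(long$AMT), num(long$DUR),
                num(long$DV), long$MDV, num(long$AGE), num(long$WT),
                long$SEX, long$ARM, num(long$BSER), sep = ",")
  writeLines(body, con)
  invisible(path)
}

# small order-stable hash of a design (or any list) for provenance lines
.config_hash <- function(x) {
  if (is.null(x)) return("none")
  s <- paste(utils::capture.output(utils::str(x, digits.d = 10)),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Read a long-format trial dataset CSV
#'
#' Parses and validates a CSV written by [write_trial_dataset()] (or any
#' file following the same schema). Validation is strict: all schema
#' columns must be present, numeric fields must parse, every observation
#' must belong to a subject with demographic data, and each subject must
#' have a baseline observation row at time 0.
#'
#' @param path CSV path.
#' @return A `trial_dataset` (list of `demographics`, `dosing`,
#'   `observations` tibbles).
#' @export
read_trial_dataset <- function(path) {
  if (!file.exists(path)) {
    stop("read_trial_dataset: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, comment.char = "#", colClasses = "character",
                         check.names = TRUE)
  need <- c("ID", "TIME", "AMT", "DUR", "DV", "MDV", "AGE", "WT", "SEX",
            "ARM")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("read_trial_dataset: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_num <- function(col, allow_na = FALSE) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) & !(allow_na & raw[[col]] == "")
    if (any(bad)) {
      stop("read_trial_dataset: non-numeric value in column ", col,
           ", row ", which(bad)[1], call. = FALSE)
    }
    x
  }
  d <- tibble::tibble(
    ID = as.integer(as_num("ID")), TIME = as_num("TIME"), AMT = as_num("AMT"),
    DUR = as_num("DUR"), DV = as_num("DV", allow_na = TRUE),
    MDV = as.integer(as_num("MDV")), AGE = as_num("AGE", allow_na = TRUE),
    WT = as_num("WT", allow_na = TRUE),
    SEX = raw$SEX, ARM = raw$ARM,
    BSER = if ("BSER" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$BSER))
    } else NA_real_
  )
  dm <- dplyr::distinct(d, .data$ID, .data$AGE, .data$WT, .data$SEX,
                        .data$ARM, .data$BSER)
  if (anyDuplicated(dm$ID)) {
    stop("read_trial_dataset: inconsistent demographics within subject ",
         dm$ID[anyDuplicated(dm$ID)], call. = FALSE)
  }
  demog <- tibble::tibble(id = dm$ID, age = dm$AGE, weight = dm$WT,
                          sex = dm$SEX, baseline_serine = dm$BSER,
                          arm = dm$ARM)
  is_dose <- d$AMT > 0
  dosing <- tibble::tibble(id = d$ID[is_dose], start = d$TIME[is_dose],
                           amount_mg = d$AMT[is_dose],
                           duration = d$DUR[is_dose])
  oo <- !is_dose
  obs <- tibble::tibble(id = d$ID[oo], time = d$TIME[oo], score = d$DV[oo],
                        missing = d$MDV[oo] == 1L)
  if (any(!obs$missing & is.na(obs$score))) {
    stop("read_trial_dataset: empty DV with MDV = 0 at observation row ",
         which(!obs$missing & is.na(obs$score))[1], call. = FALSE)
  }
  orphan <- demog$id[is.na(demog$age) | is.na(demog$weight) |
                       demog$sex == "" | demog$arm == ""]
  if (length(orphan)) {
    stop("read_trial_dataset: rows for unknown subject ", orphan[1],
         " (no demographic data)", call. = FALSE)
  }
  no_base <- setdiff(demog$id, obs$id[obs$time == 0])
  if (length(no_base)) {
    stop("read_trial_dataset: subject ", no_base[1],
         " has no baseline observation at time 0", call. = FALSE)
  }
  structure(list(demographics = demog, dosing = dosing, observations = obs),
            class = "trial_dataset")
}
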