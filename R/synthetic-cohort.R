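#' Configuration for a synthetic pediatric monitoring cohort
#'
#' Bundles and validates the knobs of the cohort generator. Defaults mirror
#' the published 774-patient pediatric HDU cohort scaled to the balanced
#' modelling set: 238 patients, half with a critical illness event (CIE),
#' the CIE mix split death/CPR/PICU : sepsis = 73 : 46, an age mix of
#' roughly 43% infants (1-11 months) and 57% pediatric children (1-5
#' years) with a rare neonate, and 24 h of 1 Hz recording per patient.
#'
#' @param n_patients Number of patients.
#' @param cie_fraction Proportion of patients with a CIE, in `[0, 1]`.
#' @param cie_mix Named proportions over `death_cpr_picu` and `sepsis`;
#'   must sum to 1.
#' @param age_distribution Named proportions over `neonate` (<1 month),
#'   `infant` (1-11 months) and `pediatric` (12-60 months); must sum to 1.
#' @param record_hours Recording length in hours, at least 24 (the cohort
#'   inclusion rule). Shorter records are allowed for quick smoke runs by
#'   setting `allow_short = TRUE`, with a warning.
#' @param sample_interval Sampling interval in seconds (1 = 1 Hz).
#' @param dropout_rate Expected fraction of samples lost to sensor
#'   disconnection, in `[0, 1)`.
#' @param artifact_rate Expected transient artifact excursions (crying,
#'   coughing analogues, each under 30 s) per patient-hour.
#' @param seed Integer seed; fixed seed gives a byte-identical cohort.
#' @param allow_short Permit `record_hours < 24` (test mode).
#' @return A validated list of class `cohort_config`.
#' @examples
#' cohort_config(n_patients = 10, cie_fraction = 0)
#' @export
cohort_config <- function(n_patients = 238,
                          cie_fraction = 0.5,
                          cie_mix = c(death_cpr_picu = 73 / 119,
                                      sepsis = 46 / 119),
                          age_distribution = c(neonate = 1, infant = 330,
                                               pediatric = 443) / 774,
                          record_hours = 24,
                          sample_interval = 1,
                          dropout_rate = 0.05,
                          artifact_rate = 2,
                          seed = 1L,
                          allow_short = FALSE) {
  stopifnot(n_patients >= 1, sample_interval > 0)
  if (cie_fraction < 0 || cie_fraction > 1) {
    stop("cie_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  if (abs(sum(cie_mix) - 1) > 1e-8 || any(cie_mix < 0)) {
    stop("cie_mix must be non-negative proportions summing to 1", call. = FALSE)
  }
  if (abs(sum(age_distribution) - 1) > 1e-8 || any(age_distribution < 0)) {
    stop("age_distribution must be non-negative proportions summing to 1",
         call. = FALSE)
  }
  if (record_hours < 24) {
    if (!allow_short) {
      stop("record_hours must be >= 24 (set allow_short = TRUE for smoke runs)",
           call. = FALSE)
    }
    warning("record_hours < 24: shorter than the cohort inclusion rule",
            call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), cie_fraction = cie_fraction,
         cie_mix = cie_mix, age_distribution = age_distribution,
         record_hours = record_hours, sample_interval = sample_interval,
         dropout_rate = dropout_rate, artifact_rate = artifact_rate,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default pre-event alarm pattern specifications
#'
#' The value ranges planted in the pre-event window of synthetic CIE
#' patients, per signal, bound and event type. They encode the cluster
#' ranges observed under each cut-off setting in the originating study:
#' for death/CPR/PICU under WHO, ECGRR upper 40-60 and lower 0-20, ECGHR
#' lower 80-85 and upper 140-160, SPO2 85-90; for sepsis under WHO, ECGRR
#' upper 40-50 and lower 0-20, ECGHR upper 150-180, SPO2 85; with GOAL3
#' analogues. Values are drawn uniformly from `[value_lo, value_hi]`;
#' only draws that actually cross the patient's own age cut-off register
#' as alarms downstream.
#'
#' @param organization `"WHO"` or `"GOAL3"`.
#' @param burst_rate Planted episodes per hour inside the onset window.
#' @param typical_duration Mean episode duration, seconds (most planted
#'   episodes stay under 30 s).
#' @param onset_window Hours before the event in which patterns appear
#'   (at most 8).
#' @return Tibble: `cie_type`, `signal`, `bound`, `value_lo`, `value_hi`,
#'   `typical_duration`, `onset_window`, `burst_rate`.
#' @export
default_pattern_specs <- function(organization = c("WHO", "GOAL3"),
                                  burst_rate = 6, typical_duration = 10,
                                  onset_window = 8) {
  organization <- toupper(organization[[1]])
  stopifnot(onset_window <= 8, typical_duration > 0)
  who <- tibble::tribble(
    ~cie_type,         ~signal, ~bound,  ~value_lo, ~value_hi,
    "death_cpr_picu",  "ECGRR", "upper",        40,        60,
    "death_cpr_picu",  "ECGRR", "lower",         0,        20,
    "death_cpr_picu",  "ECGHR", "lower",        80,        85,
    "death_cpr_picu",  "ECGHR", "upper",       140,       160,
    "death_cpr_picu",  "SPO2",  "lower",        85,        90,
    "sepsis",          "ECGRR", "upper",        40,        50,
    "sepsis",          "ECGRR", "lower",         0,        20,
    "sepsis",          "ECGHR", "upper",       150,       180,
    "sepsis",          "SPO2",  "lower",        85,        85
  )
  goal3 <- tibble::tribble(
    ~cie_type,         ~signal, ~bound,  ~value_lo, ~value_hi,
    "death_cpr_picu",  "ECGRR", "upper",        50,        70,
    "death_cpr_picu",  "ECGRR", "lower",         0,        20,
    "death_cpr_picu",  "ECGHR", "lower",        70,        85,
    "death_cpr_picu",  "ECGHR", "upper",       150,       175,
    "death_cpr_picu",  "SPO2",  "lower",        90,        90,
    "sepsis",          "ECGRR", "upper",        40,        50,
    "sepsis",          "ECGRR", "lower",         0,        20,
    "sepsis",          "ECGHR", "upper",       170,       200,
    "sepsis",          "SPO2",  "lower",        90,        90
  )
  specs <- if (organization == "WHO") who else goal3
  tibble::add_column(specs, typical_duration = typical_duration,
                     onset_window = onset_window, burst_rate = burst_rate)
}

# Age-appropriate baseline = midpoint of the WHO normal band (guarantees a
# null patient stays alarm-free). SPO2 has no upper limit; 97% is used.
signal_baseline <- function(age_months, signal,
                            cutoffs = builtin_cutoffs("WHO")) {
  row <- dplyr::filter(cutoffs_for_age(age_months, cutoffs),
                       .data$signal == !!signal)
  if (signal == "SPO2") return(97)
  (row$lower + row$upper) / 2
}

signal_band <- function(age_months, signal,
                        cutoffs = builtin_cutoffs("WHO")) {
  row <- dplyr::filter(cutoffs_for_age(age_months, cutoffs),
                       .data$signal == !!signal)
  if (signal == "SPO2") return(c(row$lower, 100))
  c(row$lower, row$upper)
}

#' Simulate one patient's vital-sign stream
#'
#' Each signal is a stationary AR(1) process around an age-appropriate
#' baseline (the midpoint of the WHO normal band; 97% for SPO2), clipped to
#' the normal band so an artifact-free, pattern-free patient never alarms.
#' SPO2 is additionally clipped to `[0, 100]`.
#'
#' @param age_months Patient age in months.
#' @param hours Recording length in hours (> 0).
#' @param interval Sampling interval in seconds.
#' @param seed Integer seed.
#' @param noise_sd Stationary standard deviation of each signal's
#'   fluctuation, as a fraction of the half-width of its normal band.
#'   `0` gives a constant baseline.
#' @param start Epoch-seconds timestamp of the first sample.
#' @return Tibble: `timestamp` (epoch seconds), `ecghr`, `ecgrr`, `spo2`.
#' @examples
#' s <- generate_vital_series(6, hours = 1, seed = 7)
#' nrow(s) # 3600
#' @export
generate_vital_series <- function(age_months, hours, interval = 1, seed = 1L,
                                  noise_sd = 0.25, start = 0) {
  stopifnot(hours > 0, interval > 0)
  n <- as.integer(round(hours * 3600 / interval))
  ts <- start + seq_len(n) * interval - interval
  withr::with_seed(seed, {
    sim <- function(signal) {
      band <- signal_band(age_months, signal)
      base <- signal_baseline(age_months, signal)
      half <- min(base - band[1], band[2] - base)
      sd_x <- noise_sd * half
      if (sd_x == 0) {
        x <- rep(base, n)
      } else {
        phi <- 0.995
        innov <- stats::rnorm(n, 0, sd_x * sqrt(1 - phi^2))
        x <- base + as.numeric(stats::filter(innov, phi, method = "recursive"))
        x <- pmin(pmax(x, band[1]), band[2])
      }
      if (signal == "SPO2") x <- pmin(pmax(x, 0), 100)
      x
    }
    tibble::tibble(timestamp = ts, ecghr = sim("ECGHR"), ecgrr = sim("ECGRR"),
                   spo2 = sim("SPO2"))
  })
}

#' Remove samples to emulate sensor disconnection
#'
#' A seeded Bernoulli mask sets the chosen fraction of each signal's
#' samples to `NA`; timestamps are untouched, so downstream episode
#' detection sees gaps that terminate alarm runs.
#'
#' @param series A vital-series tibble (see [generate_vital_series()]).
#' @param rate Expected fraction of samples dropped, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The series with missing samples.
#' @export
inject_dropout <- function(series, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(series)
  withr::with_seed(seed, {
    for (col in c("ecghr", "ecgrr", "spo2")) {
      drop <- stats::runif(nrow(series)) < rate
      series[[col]][drop] <- NA_real_
    }
  })
  series
}

# Overwrite stretches of one signal with planted alarm episodes. Episode
# starts are a Poisson process at burst_rate/h inside
# [anchor - onset_window, anchor); each episode holds one value drawn from
# [value_lo, value_hi] for a duration around typical_duration.
plant_episodes <- function(series, spec_row, anchor, interval) {
  col <- c(ECGHR = "ecghr", ECGRR = "ecgrr", SPO2 = "spo2")[[spec_row$signal]]
  win_lo <- anchor - spec_row$onset_window * 3600
  n_ep <- stats::rpois(1, spec_row$burst_rate * spec_row$onset_window)
  if (n_ep == 0) return(series)
  starts <- sort(stats::runif(n_ep, win_lo, anchor))
  durs <- pmax(1, round(stats::rnorm(n_ep, spec_row$typical_duration,
                                     spec_row$typical_duration / 3)))
  vals <- stats::runif(n_ep, spec_row$value_lo, spec_row$value_hi)
  t0 <- series$timestamp[1]
  n <- nrow(series)
  for (k in seq_len(n_ep)) {
    i0 <- floor((starts[k] - t0) / interval) + 1
    i1 <- min(n, i0 + ceiling(durs[k] / interval) - 1)
    if (i0 < 1 || i0 > n) next
    series[[col]][i0:i1] <- vals[k]
  }
  series
}

# Short excursions beyond the patient's own cut-offs, anywhere in the
# record, at artifact_rate per hour: the crying/coughing analogue.
plant_artifacts <- function(series, age_months, rate, interval,
                            cutoffs = builtin_cutoffs("WHO")) {
  hours <- nrow(series) * interval / 3600
  n_art <- stats::rpois(1, rate * hours)
  if (n_art == 0) return(series)
  lims <- cutoffs_for_age(age_months, cutoffs)
  sides <- tibble::tibble(
    signal = rep(lims$signal, 2),
    bound = rep(c("upper", "lower"), each = nrow(lims)),
    cutoff = c(lims$upper, lims$lower)
  )
  sides <- sides[!is.na(sides$cutoff), ]
  n <- nrow(series)
  for (k in seq_len(n_art)) {
    row <- sides[sample.int(nrow(sides), 1), ]
    dur <- sample(2:25, 1)                      # always under 30 s
    i0 <- sample.int(max(1, n - dur), 1)
    off <- stats::runif(1, 1, if (row$signal == "SPO2") 8 else 15)
    val <- if (row$bound == "upper") row$cutoff + off else row$cutoff - off
    if (row$signal == "SPO2") val <- max(val, 0)
    col <- c(ECGHR = "ecghr", ECGRR = "ecgrr", SPO2 = "spo2")[[row$signal]]
    series[[col]][i0:(i0 + dur - 1)] <- val
  }
  series
}

sample_age_months <- function(n, age_distribution) {
  cls <- sample(names(age_distribution), n, replace = TRUE,
                prob = age_distribution)
  vapply(cls, function(c) {
    switch(c,
           neonate = 0L,
           infant = sample(1:11, 1),
           pediatric = sample(12:60, 1))
  }, integer(1), USE.NAMES = FALSE)
}

#' Generate a synthetic cohort with planted pre-event alarm patterns
#'
#' Draws patient ages and CIE labels from the configured mixes, simulates
#' each patient's vital-sign stream, plants the event-specific alarm
#' patterns inside the onset window before the (randomly placed) event
#' time, sprinkles transient artifacts, and finally applies sensor
#' dropout. Event times are at least 8 h after recording start, so the
#' full pre-event window always exists. Deterministic for a fixed config
#' seed.
#'
#' @param config A [cohort_config()].
#' @param pattern_specs Pattern tibble (see [default_pattern_specs()]);
#'   must cover every `cie_type` with non-zero mix.
#' @param cutoffs Cut-off table used for baselines and artifact placement.
#' @return A list of class `synthetic_cohort` with elements
#'   `manifest` (tibble: `patient_id`, `age_months`, `sex`, `cie_type`,
#'   `cie_time`, `rec_start`, `rec_end`) and `series` (named list of
#'   vital-series tibbles).
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 3, cie_fraction = 0,
#'                                      record_hours = 24, seed = 5))
#' coh$manifest
#' @export
generate_cohort <- function(config,
                            pattern_specs = default_pattern_specs("WHO"),
                            cutoffs = builtin_cutoffs("WHO")) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(pattern_specs$onset_window > config$record_hours)) {
    stop("pattern onset_window exceeds record_hours", call. = FALSE)
  }
  active <- names(config$cie_mix)[config$cie_mix > 0]
  if (config$cie_fraction > 0 &&
      !all(active %in% unique(pattern_specs$cie_type))) {
    stop("pattern_specs must cover every cie_type with non-zero mix",
         call. = FALSE)
  }
  n <- config$n_patients
  withr::with_seed(config$seed, {
    meta <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      age_months = sample_age_months(n, config$age_distribution),
      sex = sample(c("male", "female"), n, replace = TRUE,
                   prob = c(0.58, 0.42)),
      cie_type = ifelse(stats::runif(n) < config$cie_fraction,
                        sample(names(config$cie_mix), n, replace = TRUE,
                               prob = config$cie_mix),
                        "none"),
      patient_seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  rec_len <- config$record_hours * 3600
  patients <- purrr::pmap(meta, function(patient_id, age_months, sex,
                                         cie_type, patient_seed) {
    withr::with_seed(patient_seed, {
      series <- generate_vital_series(age_months, config$record_hours,
                                      config$sample_interval,
                                      seed = stats::runif(1) * 1e9)
      cie_time <- NA_real_
      if (cie_type != "none") {
        cie_time <- floor(stats::runif(1, 8 * 3600, rec_len))
        specs <- dplyr::filter(pattern_specs, .data$cie_type == !!cie_type)
        for (i in seq_len(nrow(specs))) {
          series <- plant_episodes(series, specs[i, ], cie_time,
                                   config$sample_interval)
        }
      }
      series <- plant_artifacts(series, age_months, config$artifact_rate,
                                config$sample_interval, cutoffs)
      if (config$dropout_rate > 0) {
        series <- inject_dropout(series, config$dropout_rate,
                                 seed = stats::runif(1) * 1e9)
      }
      list(series = series, cie_time = cie_time)
    })
  })
  manifest <- dplyr::mutate(
    dplyr::select(meta, -"patient_seed"),
    cie_time = purrr::map_dbl(patients, "cie_time"),
    rec_start = 0, rec_end = rec_len
  )
  structure(list(manifest = manifest,
                 series = stats::setNames(purrr::map(patients, "series"),
                                          manifest$patient_id)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$manifest), " patients (",
      sum(x$manifest$cie_type != "none"), " with CIE)\n", sep = "")
  print(dplyr::count(x$manifest, .data$cie_type))
  invisible(x)
}
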