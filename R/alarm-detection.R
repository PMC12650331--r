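#' Detect threshold-alarm episodes in a vital-sign stream
#'
#' A sample violates a cut-off when its value is strictly above the upper
#' limit or strictly below the lower limit for the patient's age group;
#' values equal to a limit are normal. Maximal runs of consecutive
#' violating samples on the same side of the same signal form one episode.
#' A missing sample or a timestamp gap wider than the sample interval
#' terminates the run — disconnection intervals never get bridged into a
#' single long alarm.
#'
#' Episode duration is the number of member samples times the sample
#' interval (a single violating 1 Hz sample lasts 1 s), and the
#' representative value is the median of the run's values, which reflects
#' the signal level during the alarm rather than the limit it crossed.
#'
#' @param series Vital-series tibble with columns `timestamp`, `ecghr`,
#'   `ecgrr`, `spo2` (see [generate_vital_series()]); extra columns are
#'   ignored.
#' @param age_months Patient age in months.
#' @param cutoffs A cut-off tibble from [builtin_cutoffs()].
#' @param patient_id Identifier stamped on the output rows.
#' @param interval Sample interval in seconds; gaps larger than this split
#'   episodes.
#' @return Tibble sorted by start time: `patient_id`, `organization`,
#'   `signal`, `bound`, `start`, `end` (epoch seconds of first/last member
#'   sample), `n_samples`, `duration_s`, `rep_value`, `cutoff`.
#' @examples
#' s <- tibble::tibble(timestamp = 0:4, ecghr = c(150, 165, 170, 168, 150),
#'                     ecgrr = 30, spo2 = 98)
#' detect_episodes(s, age_months = 6, builtin_cutoffs("WHO"))
#' @export
detect_episodes <- function(series, age_months, cutoffs,
                            patient_id = "patient", interval = 1) {
  if (nrow(series) == 0) return(empty_episodes())
  lims <- cutoffs_for_age(age_months, cutoffs)
  org <- lims$organization[1]
  cols <- c(ECGHR = "ecghr", ECGRR = "ecgrr", SPO2 = "spo2")
  out <- purrr::map(seq_len(nrow(lims)), function(i) {
    sig <- lims$signal[i]
    x <- series[[cols[[sig]]]]
    purrr::map(c("upper", "lower"), function(side) {
      lim <- if (side == "upper") lims$upper[i] else lims$lower[i]
      if (is.na(lim)) return(NULL)
      viol <- if (side == "upper") x > lim else x < lim
      episodes_from_runs(viol, series$timestamp, x, interval, patient_id,
                         org, sig, side, lim)
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(out))
  if (nrow(res) == 0) return(empty_episodes())
  dplyr::arrange(res, .data$start, .data$signal, .data$bound)
}

empty_episodes <- function() {
  tibble::tibble(patient_id = character(), organization = character(),
                 signal = character(), bound = character(), start = double(),
                 end = double(), n_samples = integer(), duration_s = double(),
                 rep_value = double(), cutoff = double())
}

# Group a logical violation vector (NA = missing sample) into maximal runs,
# breaking at missing samples and at timestamp gaps > interval.
episodes_from_runs <- function(viol, ts, x, interval, patient_id, org,
                               sig, side, lim) {
  ok <- !is.na(viol) & viol
  if (!any(ok)) return(NULL)
  gap_before <- c(FALSE, diff(ts) > interval + 1e-9)
  # new run when state flips to violating, or a gap interrupts a run
  new_run <- ok & (!c(FALSE, ok[-length(ok)]) | gap_before)
  run_id <- cumsum(new_run)
  run_id[!ok] <- NA
  idx <- which(ok)
  runs <- unname(split(idx, run_id[idx]))
  tibble::tibble(
    patient_id = patient_id, organization = org, signal = sig, bound = side,
    start = vapply(runs, function(i) ts[i[1]], double(1)),
    end = vapply(runs, function(i) ts[i[length(i)]], double(1)),
    n_samples = vapply(runs, length, integer(1)),
    duration_s = vapply(runs, length, integer(1)) * interval,
    rep_value = vapply(runs, function(i) stats::median(x[i]), double(1)),
    cutoff = lim
  )
}

#' Detect episodes for every patient of a cohort
#'
#' Convenience wrapper running [detect_episodes()] across a
#' `synthetic_cohort` (or any manifest + series list) and binding the
#' results.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param cutoffs Cut-off tibble.
#' @return One episode tibble for the whole cohort.
#' @export
detect_cohort_episodes <- function(cohort, cutoffs = builtin_cutoffs("WHO")) {
  m <- cohort$manifest
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    detect_episodes(cohort$series[[m$patient_id[i]]], m$age_months[i],
                    cutoffs, patient_id = m$patient_id[i])
  })
  dplyr::bind_rows(res)
}

#' Aggregate per-signal alarm counts into a summary table
#'
#' Takes already-tallied alarm counts (one row per organization, CIE
#' stratum and signal) and computes stratum totals, each stratum's share
#' of its organization's total, and each signal's share of its stratum,
#' with percentages rounded to the nearest integer — the arithmetic layer
#' of the cohort-level alarm summary.
#'
#' @param counts Tibble with columns `organization`, `group` (e.g.
#'   `"with CIE"` / `"without CIE"` or `"all"`), `signal`, `n_alarms`.
#' @return Tibble with `organization`, `group`, `signal` (plus a
#'   `"TOTAL"` signal row per stratum), `n_alarms`, `pct_of_stratum`
#'   (integer percent of the stratum total; `NA` on total rows),
#'   `pct_of_org` (stratum total as integer percent of the organization
#'   total; filled on total rows).
#' @export
summarize_alarm_counts <- function(counts) {
  stopifnot(all(c("organization", "group", "signal", "n_alarms") %in%
                  names(counts)))
  strat <- dplyr::summarise(
    dplyr::group_by(counts, .data$organization, .data$group),
    stratum_total = sum(.data$n_alarms), .groups = "drop")
  # an "all" stratum is the union of the others: it defines the
  # organization total rather than adding to it
  org_tot <- dplyr::summarise(
    dplyr::group_by(strat, .data$organization),
    org_total = if (any(.data$group == "all"))
      .data$stratum_total[.data$group == "all"][1]
    else sum(.data$stratum_total),
    .groups = "drop")
  per_sig <- dplyr::mutate(
    dplyr::left_join(counts, strat, by = c("organization", "group")),
    pct_of_stratum = as.integer(round(100 * .data$n_alarms /
                                        .data$stratum_total)),
    pct_of_org = NA_integer_
  )
  tot_rows <- dplyr::mutate(
    dplyr::left_join(strat, org_tot, by = "organization"),
    signal = "TOTAL", n_alarms = .data$stratum_total,
    pct_of_stratum = NA_integer_,
    pct_of_org = as.integer(round(100 * .data$stratum_total /
                                    .data$org_total))
  )
  out <- dplyr::bind_rows(
    dplyr::select(per_sig, "organization", "group", "signal", "n_alarms",
                  "pct_of_stratum", "pct_of_org"),
    dplyr::select(tot_rows, "organization", "group", "signal", "n_alarms",
                  "pct_of_stratum", "pct_of_org")
  )
  dplyr::arrange(out, .data$organization, .data$group,
                 .data$signal != "TOTAL", .data$signal)
}

#' Summarise detected alarms overall and by CIE status
#'
#' Counts episodes per signal, overall and stratified by whether the
#' patient had a critical illness event, and derives the percentage
#' arithmetic via [summarize_alarm_counts()].
#'
#' @param episodes Episode tibble from [detect_episodes()].
#' @param manifest Cohort manifest with `patient_id` and `cie_type`.
#' @return Summary tibble (see [summarize_alarm_counts()]); all-zero rows
#'   when `episodes` is empty.
#' @export
summarize_alarms <- function(episodes, manifest) {
  status <- dplyr::transmute(
    manifest, .data$patient_id,
    group = ifelse(.data$cie_type == "none", "without CIE", "with CIE"))
  base <- tidyr::expand_grid(
    organization = unique(c(episodes$organization, "WHO")),
    group = c("with CIE", "without CIE"),
    signal = c("ECGHR", "ECGRR", "SPO2"))
  tallied <- dplyr::count(
    dplyr::left_join(episodes, status, by = "patient_id"),
    .data$organization, .data$group, .data$signal, name = "n_alarms")
  counts <- dplyr::mutate(
    dplyr::left_join(base, tallied,
                     by = c("organization", "group", "signal")),
    n_alarms = tidyr::replace_na(.data$n_alarms, 0L))
  summarize_alarm_counts(counts)
}
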