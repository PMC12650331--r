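#' Published alarm counts for the originating pediatric HDU cohort
#'
#' Per-signal threshold-alarm counts reported for the 774-patient
#' pediatric high-dependency-unit cohort from which the built-in WHO and
#' GOAL3 cut-off tables derive, stratified by critical-illness-event
#' status. These counts are inputs for arithmetic-consistency checks:
#' feeding them through [summarize_alarm_counts()] must reproduce the
#' reported totals (3,910,083 alarms under WHO cut-offs; 2,041,740 under
#' GOAL3) and stratum percentages.
#'
#' The `"all"` stratum carries the organization-level per-signal counts as
#' published; note the published GOAL3 without-CIE per-signal counts sum to
#' one less than the published stratum total (1,143,373 vs 1,143,374), a
#' rounding artifact of the source tabulation.
#'
#' @return Tibble: `organization`, `group`, `signal`, `n_alarms`.
#' @examples
#' summarize_alarm_counts(reference_alarm_counts())
#' @export
reference_alarm_counts <- function() {
  tibble::tribble(
    ~organization, ~group,        ~signal, ~n_alarms,
    "WHO",         "all",         "ECGHR",   1385758,
    "WHO",         "all",         "ECGRR",   2258952,
    "WHO",         "all",         "SPO2",     265373,
    "GOAL3",       "all",         "ECGHR",    409617,
    "GOAL3",       "all",         "ECGRR",   1429633,
    "GOAL3",       "all",         "SPO2",     202490,
    "WHO",         "without CIE", "ECGHR",    459826,
    "WHO",         "without CIE", "ECGRR",   1554649,
    "WHO",         "without CIE", "SPO2",     175172,
    "WHO",         "with CIE",    "ECGHR",    361292,
    "WHO",         "with CIE",    "ECGRR",   1221510,
    "WHO",         "with CIE",    "SPO2",     137634,
    "GOAL3",       "without CIE", "ECGHR",    248109,
    "GOAL3",       "without CIE", "ECGRR",    811796,
    "GOAL3",       "without CIE", "SPO2",      83468,
    "GOAL3",       "with CIE",    "ECGHR",    188657,
    "GOAL3",       "with CIE",    "ECGRR",    637840,
    "GOAL3",       "with CIE",    "SPO2",      71869
  )
}

#' Published cohort composition for the originating pediatric HDU cohort
#'
#' Patient counts by critical-illness-event category as reported for the
#' 774-patient cohort: 240 patients (31%) had any CIE; the modelled
#' classes comprise 54 death-and-CPR, 19 PICU-transfer and 46 sepsis
#' patients, i.e. 119 patients in the balanced modelling set (73
#' death/CPR/PICU + 46 sepsis).
#'
#' @return Tibble: `category`, `n`.
#' @export
reference_cohort_counts <- function() {
  tibble::tribble(
    ~category,        ~n,
    "total",         774,
    "with_cie",      240,
    "without_cie",   533,
    "death_and_cpr",  54,
    "picu",           19,
    "sepsis",         46
  )
}
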