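#' Built-in age cut-off tables for threshold alarm generation
#'
#' Returns the per-age-group vital-sign limits used to trigger threshold
#' alarms, as published for the WHO guideline settings and the GOAL3
#' monitor settings. A sample is alarming when it goes strictly above the
#' upper limit or strictly below the lower limit for the patient's age
#' group; values equal to a limit are normal. SPO2 carries a lower limit
#' only (90% for every age group).
#'
#' Age groups are half-open intervals in months. The WHO table stops at the
#' 3-4 year band; that band is extended upwards so every age resolves to a
#' row. GOAL3 has an explicit over-4-years band.
#'
#' @param organization `"WHO"` or `"GOAL3"`.
#'
#' @return A tibble with one row per age group and signal:
#'   `organization`, `age_group`, `age_lo` / `age_hi` (months, half-open
#'   `[lo, hi)`), `signal` (`ECGHR`, `ECGRR`, `SPO2`), `lower`, `upper`
#'   (`NA` where the side is not monitored).
#' @examples
#' builtin_cutoffs("WHO")
#' @export
builtin_cutoffs <- function(organization = c("WHO", "GOAL3")) {
  organization <- toupper(organization[[1]])
  if (!organization %in% c("WHO", "GOAL3")) {
    stop("unknown organization '", organization, "'; valid options: WHO, GOAL3",
         call. = FALSE)
  }
  if (organization == "WHO") {
    groups <- tibble::tribble(
      ~age_group,  ~age_lo, ~age_hi, ~hr_up, ~hr_lo, ~spo2_lo, ~rr_up, ~rr_lo,
      "<1 year",        0,      12,    160,    100,       90,     50,     20,
      "1-3 years",     12,      36,    150,     90,       90,     40,     10,
      "3-4 years",     36,     Inf,    140,     80,       90,     40,     10
    )
  } else {
    groups <- tibble::tribble(
      ~age_group,  ~age_lo, ~age_hi, ~hr_up, ~hr_lo, ~spo2_lo, ~rr_up, ~rr_lo,
      "<1 year",        0,      12,    200,     80,       90,     60,     20,
      "1-3 years",     12,      36,    180,     80,       90,     50,     20,
      "3-4 years",     36,      48,    170,     70,       90,     50,     20,
      ">4 years",      48,     Inf,    170,     70,       90,     40,     20
    )
  }
  long <- dplyr::bind_rows(
    dplyr::transmute(groups, .data$age_group, .data$age_lo, .data$age_hi,
                     signal = "ECGHR", lower = .data$hr_lo, upper = .data$hr_up),
    dplyr::transmute(groups, .data$age_group, .data$age_lo, .data$age_hi,
                     signal = "ECGRR", lower = .data$rr_lo, upper = .data$rr_up),
    dplyr::transmute(groups, .data$age_group, .data$age_lo, .data$age_hi,
                     signal = "SPO2", lower = .data$spo2_lo, upper = NA_real_)
  )
  dplyr::arrange(
    tibble::add_column(long, organization = organization, .before = 1),
    .data$age_lo, .data$signal
  )
}

#' Assign a patient to an age group of a cut-off table
#'
#' Groups are half-open `[age_lo, age_hi)` in months, so a child of exactly
#' 12 months falls in the 1-3 year band. The top band is open-ended: ages
#' above the table's last boundary resolve to it (for WHO this extends the
#' 3-4 year band upwards).
#'
#' @param age_months Age in months (vectorised, each `>= 0`).
#' @param cutoffs A cut-off tibble from [builtin_cutoffs()].
#' @return Character vector of age-group keys.
#' @examples
#' assign_age_group(6, builtin_cutoffs("WHO"))
#' @export
assign_age_group <- function(age_months, cutoffs) {
  stopifnot(all(age_months >= 0))
  bands <- dplyr::distinct(cutoffs, .data$age_group, .data$age_lo, .data$age_hi)
  bands <- dplyr::arrange(bands, .data$age_lo)
  idx <- findInterval(age_months, bands$age_lo)
  bands$age_group[idx]
}

# Limits for one age: named list of rows (signal -> lower/upper)
cutoffs_for_age <- function(age_months, cutoffs) {
  grp <- assign_age_group(age_months, cutoffs)
  dplyr::filter(cutoffs, .data$age_group == grp)
}
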