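#' Restrict alarms to the window preceding each critical illness event
#'
#' Keeps episodes whose start time lies in `[event_time - window,
#' event_time)` for the patient's anchoring event. Membership uses the
#' episode start only: an episode straddling the window's left edge is
#' included iff it starts inside, and one starting exactly at the event is
#' excluded (half-open right edge). Patients with several events are
#' anchored at their earliest.
#'
#' @param episodes Episode tibble (see [detect_episodes()]).
#' @param events Tibble with `patient_id`, `cie_type`, `event_time`
#'   (epoch seconds). Use [pseudo_events()] to give event-free patients a
#'   comparison window.
#' @param window_hours Window length in hours (> 0), default 8.
#' @return The windowed episodes with added columns `cie_type`,
#'   `event_time` and `lead_time_s` (= `event_time - start`, positive).
#' @export
window_alarms <- function(episodes, events, window_hours = 8) {
  stopifnot(window_hours > 0)
  anchors <- dplyr::slice_min(dplyr::group_by(events, .data$patient_id),
                              .data$event_time, n = 1, with_ties = FALSE)
  joined <- dplyr::inner_join(episodes, dplyr::ungroup(anchors),
                              by = "patient_id")
  win <- window_hours * 3600
  out <- dplyr::filter(joined, .data$start >= .data$event_time - win,
                       .data$start < .data$event_time)
  dplyr::mutate(out, lead_time_s = .data$event_time - .data$start)
}

#' Pseudo-anchor events for patients without a critical illness event
#'
#' Event-free patients get a comparison window anchored at the recording
#' midpoint (or its end), so their alarm patterns can be summarised and
#' fed to the classifier alongside true pre-event windows.
#'
#' @param manifest Cohort manifest with `patient_id`, `cie_type`,
#'   `cie_time`, `rec_start`, `rec_end`.
#' @param anchor `"midpoint"` or `"end"` of the recording for event-free
#'   patients.
#' @return Events tibble (`patient_id`, `cie_type`, `event_time`) covering
#'   every patient: true event times where present, pseudo-anchors
#'   elsewhere.
#' @export
pseudo_events <- function(manifest, anchor = c("midpoint", "end")) {
  anchor <- match.arg(anchor)
  dplyr::transmute(
    manifest, .data$patient_id, cie_type = .data$cie_type,
    event_time = dplyr::if_else(
      .data$cie_type != "none", .data$cie_time,
      if (anchor == "midpoint") (.data$rec_start + .data$rec_end) / 2
      else .data$rec_end))
}

#' Summarise windowed alarms over equal pre-event time segments
#'
#' Splits the pre-event window into `n_segments` equal segments (segment 1
#' is the earliest, e.g. `[-8 h, -6 h)` for the default 8 h window in
#' four segments) and tallies, per segment: episode counts by signal and
#' bound, a duration histogram, and the fraction of episodes shorter than
#' 30 s. Episodes are assigned by start time and never split across
#' segment boundaries.
#'
#' @param windowed Output of [window_alarms()] (must carry `lead_time_s`
#'   within the window).
#' @param window_hours Window length in hours, matching the windowing call.
#' @param n_segments Number of equal segments (>= 1), default 4.
#' @param breaks Duration histogram edges in seconds.
#' @param by_patient Tally per patient as well as per segment.
#' @return Tibble of per-segment counts: `segment_index`, `segment_lo_h`,
#'   `segment_hi_h` (hours before the event), `signal`, `bound`, `n`,
#'   `fraction_under_30s`, plus `duration_hist` (list column of named
#'   bin counts). Empty input yields all-zero rows for every segment.
#' @export
segment_summary <- function(windowed, window_hours = 8, n_segments = 4,
                            breaks = c(0, 10, 20, 30, 60, 120, Inf),
                            by_patient = FALSE) {
  stopifnot(n_segments >= 1)
  win <- window_hours * 3600
  if (nrow(windowed) > 0 &&
      (any(windowed$lead_time_s <= 0) || any(windowed$lead_time_s > win))) {
    stop("episodes outside the window; run window_alarms() first",
         call. = FALSE)
  }
  seg_len <- win / n_segments
  # lead time decreases toward the event; segment 1 is the earliest
  seg_of <- function(lead) pmin(n_segments,
                                n_segments - floor(lead / seg_len))
  base <- tibble::tibble(segment_index = seq_len(n_segments),
                         segment_lo_h = window_hours -
                           (seq_len(n_segments) - 1) * window_hours / n_segments,
                         segment_hi_h = window_hours -
                           seq_len(n_segments) * window_hours / n_segments)
  if (nrow(windowed) == 0) {
    return(dplyr::mutate(base, signal = NA_character_, bound = NA_character_,
                         n = 0L, fraction_under_30s = NA_real_,
                         duration_hist = list(hist_counts(numeric(), breaks))))
  }
  tagged <- dplyr::mutate(windowed,
                          segment_index = seg_of(.data$lead_time_s - 1e-9))
  keys <- if (by_patient) c("patient_id", "segment_index", "signal", "bound")
          else c("segment_index", "signal", "bound")
  tallied <- dplyr::summarise(
    dplyr::group_by(tagged, dplyr::across(dplyr::all_of(keys))),
    n = dplyr::n(),
    fraction_under_30s = mean(.data$duration_s < 30),
    duration_hist = list(hist_counts(.data$duration_s, breaks)),
    .groups = "drop")
  out <- dplyr::left_join(base, tallied, by = "segment_index")
  dplyr::mutate(out, n = tidyr::replace_na(.data$n, 0L))
}

hist_counts <- function(x, breaks) {
  cnt <- as.integer(table(cut(x, breaks, right = FALSE,
                              include.lowest = FALSE)))
  names(cnt) <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
  cnt
}
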