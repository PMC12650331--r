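#' Extract modal alarm-pattern features per patient, signal and bound
#'
#' For every patient x signal x bound group of windowed alarms, clusters
#' the episodes in the (representative value, duration) plane with
#' [dbscan()] and reduces the densest cluster to a modal pattern: the most
#' frequent alarm value and the most frequent duration. The mode is always
#' an observed value, never an average.
#'
#' Groups with fewer than `min_pts` episodes skip clustering and take the
#' mode over all their points (clustering would label everything noise);
#' when clustering labels every point noise the fallback is likewise all
#' points. Coordinates are standardised per dimension within the group
#' before clustering (constant dimensions are left at zero), so `eps` is
#' unit-free across signals.
#'
#' Mode ties break to the candidate closest to the median of the values
#' being summarised, then to the smaller value.
#'
#' @param windowed Windowed episode tibble (see [window_alarms()]); must
#'   carry `patient_id`, `cie_type`, `signal`, `bound`, `rep_value`,
#'   `duration_s`.
#' @param eps DBSCAN radius in the standardised plane, default 0.5.
#' @param min_pts DBSCAN core-point threshold, default 10.
#' @param space `"value-duration"` (2-D, default) or `"value"` (1-D).
#' @param scale Standardise coordinates per dimension before clustering.
#' @return Tibble with one row per group holding >= 1 alarm: `patient_id`,
#'   `cie_status`, `signal`, `bound`, `modal_value`, `modal_duration`,
#'   `n_alarms`, `largest_cluster_size`.
#' @export
extract_pattern_features <- function(windowed, eps = 0.5, min_pts = 10,
                                     space = c("value-duration", "value"),
                                     scale = TRUE) {
  space <- match.arg(space)
  if (nrow(windowed) == 0) {
    return(tibble::tibble(patient_id = character(), cie_status = character(),
                          signal = character(), bound = character(),
                          modal_value = double(), modal_duration = double(),
                          n_alarms = integer(),
                          largest_cluster_size = integer()))
  }
  grouped <- dplyr::group_by(windowed, .data$patient_id, .data$cie_type,
                             .data$signal, .data$bound)
  out <- dplyr::reframe(
    grouped, pattern_from_group(.data$rep_value, .data$duration_s, eps,
                                min_pts, space, scale))
  dplyr::rename(out, cie_status = "cie_type")[
    , c("patient_id", "cie_status", "signal", "bound", "modal_value",
        "modal_duration", "n_alarms", "largest_cluster_size")]
}

pattern_from_group <- function(values, durations, eps, min_pts, space,
                               scale) {
  n <- length(values)
  if (n >= min_pts) {
    coords <- if (space == "value") cbind(values) else cbind(values, durations)
    if (scale) coords <- apply(coords, 2, function(c) {
      s <- stats::sd(c)
      if (is.na(s) || s == 0) rep(0, length(c)) else (c - mean(c)) / s
    })
    res <- dbscan(coords, eps = eps, min_pts = min_pts)
    keep <- if (res$n_clusters == 0) rep(TRUE, n) else {
      sizes <- tabulate(res$labels[res$labels > 0], res$n_clusters)
      res$labels == which.max(sizes)    # ties -> lowest cluster id
    }
  } else {
    keep <- rep(TRUE, n)
  }
  tibble::tibble(
    modal_value = mode_value(values[keep]),
    modal_duration = mode_value(durations[keep]),
    n_alarms = n,
    largest_cluster_size = sum(keep)
  )
}

# Most frequent observed value; ties -> closest to the median of the
# summarised values, then the smaller value.
mode_value <- function(x) {
  tab <- table(x)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  if (length(cand) == 1) return(cand)
  med <- stats::median(x)
  cand <- cand[abs(cand - med) == min(abs(cand - med))]
  min(cand)
}
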