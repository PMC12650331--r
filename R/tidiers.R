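#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classifier evaluation
#'
#' One row per class and metric pair: precision, recall, F1, support and
#' one-vs-rest AUC for each reported class.
#'
#' @param x A `cie_eval` from [train_and_evaluate()].
#' @param ... Unused.
#' @return A tibble with columns `class`, `metric`, `value`.
#' @method tidy cie_eval
#' @export
tidy.cie_eval <- function(x, ...) {
  long <- tidyr::pivot_longer(x$metrics,
                              cols = c("precision", "recall", "f1",
                                       "support"),
                              names_to = "metric", values_to = "value")
  auc_rows <- tibble::tibble(
    class = names(x$auc), metric = "auc", value = as.numeric(x$auc))
  dplyr::arrange(dplyr::bind_rows(long, auc_rows), .data$class,
                 .data$metric)
}

#' Glance at a classifier evaluation
#'
#' @param x A `cie_eval` from [train_and_evaluate()].
#' @param ... Unused.
#' @return One-row tibble: `family`, `accuracy`, `auc_micro`, `n_test`.
#' @method glance cie_eval
#' @export
glance.cie_eval <- function(x, ...) {
  tibble::tibble(family = x$family, accuracy = x$accuracy,
                 auc_micro = as.numeric(x$auc[["micro"]]),
                 n_test = sum(x$confusion))
}

#' Tidy a DBSCAN result
#'
#' @param x A `dbscan_result` from [dbscan()].
#' @param ... Unused.
#' @return Tibble with `point`, `cluster` (`NA` for noise), `core`.
#' @method tidy dbscan_result
#' @export
tidy.dbscan_result <- function(x, ...) {
  tibble::tibble(point = seq_along(x$labels),
                 cluster = ifelse(x$labels == 0, NA_integer_, x$labels),
                 core = x$core)
}
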