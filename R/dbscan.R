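#' Density-based clustering of alarm points (DBSCAN)
#'
#' Classic density-based spatial clustering with Euclidean distances,
#' written for the small per-patient alarm point sets this package
#' produces. A point is a *core point* when at least `min_pts` points
#' (itself included) lie within radius `eps`; clusters are maximal sets of
#' density-connected points; points that are neither core nor within
#' `eps` of a core point are labelled noise (`0`).
#'
#' Labelling is deterministic for a fixed input order: clusters are seeded
#' in point order, so cluster ids follow the order of first discovery, and
#' a border point reachable from several clusters joins the one with the
#' lowest id.
#'
#' @param x Numeric matrix or data frame of point coordinates (rows =
#'   points); all values must be finite.
#' @param eps Neighbourhood radius (> 0), in the space of `x`.
#' @param min_pts Minimum neighbourhood size for a core point (>= 1),
#'   default 10.
#' @return A list of class `dbscan_result`: `labels` (integer per point,
#'   `0` = noise), `core` (logical per point), `n_clusters`, `eps`,
#'   `min_pts`.
#' @examples
#' pts <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 6), ncol = 2))
#' dbscan(pts, eps = 1.5, min_pts = 5)
#' @export
dbscan <- function(x, eps, min_pts = 10) {
  stopifnot(eps > 0, min_pts >= 1)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) {
    return(structure(list(labels = integer(0), core = logical(0),
                          n_clusters = 0L, eps = eps, min_pts = min_pts),
                     class = "dbscan_result"))
  }
  stopifnot(all(is.finite(x)))
  d <- as.matrix(stats::dist(x))
  nb <- d <= eps                       # neighbourhood includes the point
  core <- unname(rowSums(nb) >= min_pts)
  labels <- integer(n)                 # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      reach <- which(nb[p, ] & labels == 0L)
      labels[reach] <- cl
      queue <- c(queue, reach[core[reach]])
    }
  }
  structure(list(labels = labels, core = core, n_clusters = cl,
                 eps = eps, min_pts = min_pts),
            class = "dbscan_result")
}

#' @export
print.dbscan_result <- function(x, ...) {
  cat("<dbscan_result> ", length(x$labels), " points, ", x$n_clusters,
      " cluster(s), ", sum(x$labels == 0), " noise (eps = ", x$eps,
      ", min_pts = ", x$min_pts, ")\n", sep = "")
  invisible(x)
}
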