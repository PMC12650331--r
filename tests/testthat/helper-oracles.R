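# Independent brute-force oracles used to validate the package's episode
# detector and clusterer, plus shared fixtures.

# --- episode oracle: per-sample scan -----------------------------------------
# Walks the samples one by one, opening a run at the first violating sample
# and closing it on a non-violating value, a missing sample, or a timestamp
# gap wider than the interval. Strict inequality at the limit.
brute_episodes <- function(ts, x, lim, side, interval = 1) {
  runs <- list()
  cur <- integer()
  flush <- function() {
    if (length(cur) > 0) runs[[length(runs) + 1]] <<- cur
    cur <<- integer()
  }
  for (i in seq_along(x)) {
    gap <- i > 1 && (ts[i] - ts[i - 1]) > interval + 1e-9
    if (gap) flush()
    v <- x[i]
    viol <- !is.na(v) && ((side == "upper" && v > lim) ||
                            (side == "lower" && v < lim))
    if (viol) cur <- c(cur, i) else flush()
  }
  flush()
  if (length(runs) == 0) {
    return(data.frame(start = double(), end = double(),
                      n_samples = integer(), rep_value = double()))
  }
  data.frame(
    start = vapply(runs, function(i) ts[i[1]], 1),
    end = vapply(runs, function(i) ts[i[length(i)]], 1),
    n_samples = vapply(runs, length, 1L),
    rep_value = vapply(runs, function(i) median(x[i]), 1)
  )
}

# Random short series with missing samples and timestamp gaps, around the
# WHO infant ECGHR band so both bounds get exercised.
random_test_series <- function(n_max = 50) {
  n <- sample(1:n_max, 1)
  ts <- cumsum(sample(c(1, 1, 1, 1, 3), n, replace = TRUE))
  hr <- runif(n, 80, 180)
  hr[runif(n) < 0.15] <- NA
  tibble::tibble(timestamp = ts, ecghr = hr, ecgrr = 30, spo2 = 98)
}

# --- DBSCAN oracle: density-connected components via igraph ------------------
# Core points from the full distance matrix; clusters are the connected
# components of the core-point graph (edges at distance <= eps); border
# points attach to any core neighbour's component; the rest is noise.
brute_dbscan <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  labels <- rep(0L, n)
  comp <- rep(NA_integer_, n)
  if (any(core)) {
    g <- igraph::graph_from_adjacency_matrix(
      nb[core, core, drop = FALSE] * 1, mode = "undirected", diag = FALSE)
    comp_core <- igraph::components(g)$membership
    comp[core] <- comp_core
    labels[core] <- comp_core
    for (i in which(!core)) {
      nbr_core <- which(core & nb[i, ])
      if (length(nbr_core) > 0) labels[i] <- comp[nbr_core[1]]
    }
  }
  list(labels = labels, core = core,
       # all clusters a border point could legitimately join
       border_options = lapply(seq_len(n), function(i) {
         if (core[i]) return(comp[i])
         unique(comp[core & nb[i, ]])
       }))
}

# Checks an implementation result against the oracle: identical noise and
# core sets, a bijection between core-point clusters, and every border
# point assigned to a cluster of one of its core neighbours.
expect_dbscan_matches <- function(res, oracle) {
  expect_identical(res$core, unname(oracle$core))
  expect_identical(res$labels == 0, oracle$labels == 0)
  core <- oracle$core
  if (any(core)) {
    map <- table(oracle$labels[core], res$labels[core])
    # each oracle component maps to exactly one implementation cluster
    expect_true(all(rowSums(map > 0) == 1))
    expect_true(all(colSums(map > 0) == 1))
  }
  expect_identical(res$n_clusters,
                   length(unique(oracle$labels[oracle$core])))
  for (i in which(!core & oracle$labels != 0)) {
    opts <- oracle$border_options[[i]]
    impl_of_oracle <- vapply(opts, function(cl) {
      res$labels[core & oracle$labels == cl][1]
    }, 1L)
    expect_true(res$labels[i] %in% impl_of_oracle)
  }
}

# --- shared study-scale cohort ------------------------------------------------
# Built lazily, once per test run: the default WHO study conditions
# (238 patients, 24 h at 1 Hz, planted pre-event patterns).
.fixture_cache <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (!is.null(.fixture_cache$fix)) return(.fixture_cache$fix)
  cfg <- cohort_config(seed = 2024L)
  cohort <- generate_cohort(cfg)
  episodes <- detect_cohort_episodes(cohort)
  windowed <- window_alarms(episodes, pseudo_events(cohort$manifest))
  features <- extract_pattern_features(windowed)
  dataset <- assemble_dataset(features, cohort$manifest, balance = TRUE)
  .fixture_cache$fix <- list(cohort = cohort, episodes = episodes,
                             windowed = windowed, features = features,
                             dataset = dataset)
  .fixture_cache$fix
}

# Cleanly separable three-class feature fixture: class clusters far apart,
# no overlap — the separable limit for classifier sanity checks.
separable_dataset <- function(n_per_class = 30, seed = 99) {
  withr::with_seed(seed, {
    lab <- rep(c("none", "death_cpr_picu", "sepsis"), each = n_per_class)
    centre <- c(none = 0, death_cpr_picu = 50, sepsis = 100)[lab]
    cols <- paste0("f", 1:6)
    m <- sapply(cols, function(c) centre + runif(length(lab), -1, 1))
    out <- tibble::as_tibble(as.data.frame(m))
    out$patient_id <- sprintf("S%03d", seq_along(lab))
    out$label <- factor(lab, levels = c("none", "death_cpr_picu", "sepsis"))
    dplyr::relocate(out, "patient_id", "label")
  })
}
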