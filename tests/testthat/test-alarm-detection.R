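who <- builtin_cutoffs("WHO")

test_that("episodes match hand-enumerated runs at the published limits", {
  # infant WHO ECGHR: limit 160, strict; 165,170,168 form one 3 s episode
  s <- tibble::tibble(timestamp = 0:4, ecghr = c(150, 165, 170, 168, 150),
                      ecgrr = 30, spo2 = 98)
  ep <- detect_episodes(s, 6, who)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$bound, "upper")
  expect_equal(ep$n_samples, 3)
  expect_equal(ep$duration_s, 3)
  expect_equal(ep$rep_value, 168)
  expect_equal(ep$cutoff, 160)

  # a missing sample splits the SPO2 run (limit 90): two 1 s episodes
  s2 <- tibble::tibble(timestamp = 0:4, ecghr = 120, ecgrr = 30,
                       spo2 = c(92, 88, NA, 87, 92))
  ep2 <- detect_episodes(s2, 6, who)
  expect_equal(nrow(ep2), 2)
  expect_equal(ep2$duration_s, c(1, 1))
  expect_equal(ep2$rep_value, c(88, 87))

  # boundary values are normal: exactly 160 / exactly 90 never alarm
  s3 <- tibble::tibble(timestamp = 0:2, ecghr = c(160, 160, 160),
                       ecgrr = 30, spo2 = c(90, 90, 90))
  expect_equal(nrow(detect_episodes(s3, 6, who)), 0)

  # constant in-range series and empty series
  s4 <- tibble::tibble(timestamp = 0:9, ecghr = 120, ecgrr = 30, spo2 = 98)
  expect_equal(nrow(detect_episodes(s4, 6, who)), 0)
  expect_equal(nrow(detect_episodes(s4[0, ], 6, who)), 0)
  # an all-missing signal contributes nothing
  s5 <- dplyr::mutate(s4, spo2 = NA_real_)
  expect_equal(nrow(detect_episodes(s5, 6, who)), 0)
})

test_that("detector agrees with the per-sample brute-force oracle", {
  withr::with_seed(404, {
    for (rep in 1:200) {
      s <- random_test_series()
      ep <- detect_episodes(s, 6, who)
      hr <- dplyr::filter(ep, signal == "ECGHR")
      for (side in c("upper", "lower")) {
        lim <- if (side == "upper") 160 else 100
        want <- brute_episodes(s$timestamp, s$ecghr, lim, side)
        got <- dplyr::filter(hr, bound == side)
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$n_samples, want$n_samples)
        expect_equal(got$rep_value, want$rep_value)
        # conservation: every violating sample belongs to exactly one run
        viol <- !is.na(s$ecghr) &
          (if (side == "upper") s$ecghr > lim else s$ecghr < lim)
        expect_equal(sum(got$n_samples), sum(viol))
      }
      # disjointness: same-side episodes never overlap
      by_side <- split(hr, hr$bound)
      for (b in by_side) {
        if (nrow(b) > 1) expect_true(all(diff(b$start) > 0 &
                                           b$start[-1] > b$end[-nrow(b)]))
      }
    }
  })
})

test_that("relaxing a cut-off never increases violating samples", {
  withr::with_seed(77, {
    s <- random_test_series()
    count_viol <- function(lim) sum(s$ecghr > lim, na.rm = TRUE)
    lims <- seq(100, 200, by = 10)
    expect_true(all(diff(vapply(lims, count_viol, 1)) <= 0))
    ep_tight <- detect_episodes(s, 6, who)
    relaxed <- dplyr::mutate(who, upper = upper + 20, lower = lower - 20)
    ep_loose <- detect_episodes(s, 6, relaxed)
    expect_lte(sum(ep_loose$n_samples), sum(ep_tight$n_samples))
  })
})

test_that("alarm summaries reproduce count and percentage arithmetic", {
  sm <- summarize_alarm_counts(reference_alarm_counts())
  who_tot <- dplyr::filter(sm, organization == "WHO", group == "all",
                           signal == "TOTAL")
  expect_equal(who_tot$n_alarms, 1385758 + 2258952 + 265373)
  shares <- dplyr::filter(sm, organization == "WHO", group == "without CIE",
                          signal != "TOTAL")
  expect_equal(
    setNames(shares$pct_of_stratum, shares$signal),
    c(ECGHR = 21L, ECGRR = 71L, SPO2 = 8L))

  # single detected episode: 100% of its stratum
  one <- tibble::tibble(patient_id = "P1", organization = "WHO",
                        signal = "SPO2", bound = "lower", start = 0, end = 0,
                        n_samples = 1L, duration_s = 1, rep_value = 88,
                        cutoff = 90)
  man <- tibble::tibble(patient_id = "P1", cie_type = "none")
  sm1 <- summarize_alarms(one, man)
  got <- dplyr::filter(sm1, group == "without CIE", signal == "SPO2")
  expect_equal(got$n_alarms, 1L)
  expect_equal(got$pct_of_stratum, 100L)

  # empty input: an all-zero table, not an error
  sm0 <- summarize_alarms(empty <- one[0, ], man)
  expect_true(all(sm0$n_alarms == 0))
})
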