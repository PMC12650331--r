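test_that("configuration invariants are enforced", {
  expect_error(cohort_config(cie_fraction = 1.2), "cie_fraction")
  expect_error(cohort_config(dropout_rate = 1), "dropout_rate")
  expect_error(cohort_config(cie_mix = c(death_cpr_picu = 0.6, sepsis = 0.6)),
               "cie_mix")
  expect_error(cohort_config(record_hours = 12), "record_hours")
  expect_warning(cohort_config(record_hours = 2, allow_short = TRUE),
                 "shorter")
  cfg <- cohort_config(record_hours = 48)
  # onset window cannot exceed the recording
  short <- suppressWarnings(cohort_config(n_patients = 2, record_hours = 4,
                                          allow_short = TRUE))
  expect_error(generate_cohort(short), "onset_window")
})

test_that("zero prevalence yields an event-free cohort, deterministically", {
  cfg <- cohort_config(n_patients = 10, cie_fraction = 0, seed = 1)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$manifest), 10)
  expect_true(all(coh$manifest$cie_type == "none"))
  expect_true(all(is.na(coh$manifest$cie_time)))
  coh2 <- generate_cohort(cohort_config(n_patients = 10, cie_fraction = 0,
                                        seed = 1))
  expect_identical(coh, coh2)
  # different seed, different realisation
  coh3 <- generate_cohort(cohort_config(n_patients = 10, cie_fraction = 0,
                                        seed = 2))
  expect_false(identical(coh$series[[1]], coh3$series[[1]]))
})

test_that("CIE prevalence lands inside the binomial 99% interval", {
  cfg <- cohort_config(n_patients = 200, cie_fraction = 0.31, seed = 7)
  coh <- generate_cohort(cfg)
  n_cie <- sum(coh$manifest$cie_type != "none")
  bounds <- qbinom(c(0.005, 0.995), 200, 0.31)
  expect_gte(n_cie, bounds[1])
  expect_lte(n_cie, bounds[2])
  # event times leave room for the full 8 h pre-event window
  cie_times <- coh$manifest$cie_time[coh$manifest$cie_type != "none"]
  expect_true(all(cie_times >= 8 * 3600))
  expect_true(all(cie_times <= coh$manifest$rec_end[1]))
})

test_that("equal class mix yields balanced labels within sampling bounds", {
  cfg <- cohort_config(n_patients = 300, cie_fraction = 1,
                       cie_mix = c(death_cpr_picu = 0.5, sepsis = 0.5),
                       seed = 13)
  coh <- generate_cohort(cfg)
  n_death <- sum(coh$manifest$cie_type == "death_cpr_picu")
  bounds <- qbinom(c(0.005, 0.995), 300, 0.5)
  expect_gte(n_death, bounds[1])
  expect_lte(n_death, bounds[2])
})

test_that("vital series have the right grid, bounds and degenerate limits", {
  s <- generate_vital_series(6, hours = 24, interval = 1, seed = 7)
  expect_equal(nrow(s), 86400)
  expect_equal(diff(s$timestamp), rep(1, 86399))
  expect_true(all(s$spo2 >= 0 & s$spo2 <= 100))
  # zero noise -> constant age-appropriate baseline (WHO band midpoint)
  s0 <- generate_vital_series(6, hours = 1, seed = 1, noise_sd = 0)
  expect_true(all(s0$ecghr == 130))
  expect_true(all(s0$ecgrr == 35))
  # a null patient never alarms under the WHO cut-offs
  ep <- detect_episodes(generate_vital_series(6, hours = 2, seed = 3),
                        6, builtin_cutoffs("WHO"))
  expect_equal(nrow(ep), 0)
})

test_that("dropout removes the expected fraction and splits alarm runs", {
  s <- generate_vital_series(6, hours = 3, seed = 5)  # 10800 samples
  expect_identical(inject_dropout(s, 0, seed = 1), s)
  expect_error(inject_dropout(s, 1), "rate")
  d <- inject_dropout(s, 0.1, seed = 1)
  n_missing <- sum(is.na(d$ecghr))
  bounds <- qbinom(c(0.005, 0.995), nrow(s), 0.1)
  expect_gte(n_missing, bounds[1])
  expect_lte(n_missing, bounds[2])
  expect_identical(d$timestamp, s$timestamp)

  # a gap inside a 10 s violation splits it into two episodes downstream
  v <- tibble::tibble(timestamp = 0:9, ecghr = 170, ecgrr = 30, spo2 = 98)
  v$ecghr[5] <- NA
  ep <- detect_episodes(v, 6, builtin_cutoffs("WHO"))
  expect_equal(nrow(ep), 2)
  expect_equal(ep$n_samples, c(4, 5))
})

test_that("planted violations are recovered as episode members", {
  # no dropout, high burst rate: nearly every injected violating sample
  # must come back as part of a detected episode
  cfg <- suppressWarnings(cohort_config(
    n_patients = 6, cie_fraction = 1, record_hours = 10,
    dropout_rate = 0, artifact_rate = 0, seed = 21, allow_short = TRUE))
  specs <- default_pattern_specs("WHO", burst_rate = 12)
  coh <- generate_cohort(cfg, specs)
  who <- builtin_cutoffs("WHO")
  for (i in seq_len(nrow(coh$manifest))) {
    m <- coh$manifest[i, ]
    s <- coh$series[[m$patient_id]]
    ep <- detect_episodes(s, m$age_months, who, patient_id = m$patient_id)
    lims <- dplyr::filter(who, age_group == assign_age_group(m$age_months, who))
    for (sig in c("ECGHR", "ECGRR", "SPO2")) {
      col <- c(ECGHR = "ecghr", ECGRR = "ecgrr", SPO2 = "spo2")[[sig]]
      lim <- dplyr::filter(lims, signal == sig)
      viol <- (!is.na(lim$upper) & s[[col]] > lim$upper) |
        (!is.na(lim$lower) & s[[col]] < lim$lower)
      n_viol <- sum(viol, na.rm = TRUE)
      covered <- sum(ep$n_samples[ep$signal == sig])
      if (n_viol > 0) expect_gte(covered / n_viol, 0.95)
      expect_equal(covered, n_viol)  # in fact exact conservation
    }
  }
})
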