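test_that("configuration errors name the offending field", {
  expect_error(cohort_config(n_participants = 2, prevalence_target = 1.5),
               class = "sleepcast_config_error")
  expect_error(cohort_config(n_participants = 2, beta_arousal = 0.5),
               class = "sleepcast_config_error")
  expect_error(cohort_config(n_participants = 2, n_days = 1),
               class = "sleepcast_config_error")
  err <- tryCatch(cohort_config(n_participants = 2, noise_sd = -1),
                  error = function(e) e)
  expect_identical(err$field, "noise_sd")
})

test_that("a degenerate deterministic model yields exactly the fixed SE", {
  cfg <- cohort_config(n_participants = 3, n_days = 4, seed = 5,
                       noise_sd = 0, beta_arousal = 0,
                       beta_evening_activity = 0, beta_late_light = 0,
                       beta_prev_night = 0, beta0 = qlogis(0.93))
  tr <- generate_truth(cfg)
  expect_equal(tr$true_sleep_efficiency, rep(0.93, nrow(tr)), tolerance = 1e-12)
  expect_true(all(tr$true_good_sleep))
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- cohort_config(n_participants = 2, n_days = 3, seed = 9,
                       missingness = missingness_config(
                         p_battery_gap_per_day = 0.3,
                         p_sleeve_occlusion_per_day = 0.3))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$rri, b$rri)
  expect_identical(a$diary, b$diary)
  expect_identical(a$truth, b$truth)
})

test_that("the intercept calibration hits the target prevalence", {
  for (target in c(0.3, 0.5)) {
    tr <- generate_truth(cohort_config(n_participants = 90, n_days = 14,
                                       seed = 7, prevalence_target = target))
    got <- mean(tr$true_good_sleep[tr$in_study])
    expect_lt(abs(got - target), 0.05)
  }
})

test_that("arousal couples pNN50 and sleep efficiency in the same direction", {
  tr <- generate_truth(cohort_config(n_participants = 90, n_days = 14,
                                     seed = 8, beta_arousal = -0.8))
  expect_gt(cor(tr$target_pnn50, tr$true_sleep_efficiency), 0.2)

  # with the arousal path zeroed the pNN50 target is flat and arousal is
  # uncorrelated with sleep efficiency
  tr0 <- generate_truth(cohort_config(n_participants = 90, n_days = 14,
                                      seed = 8, beta_arousal = 0,
                                      beta_evening_activity = 0,
                                      beta_late_light = 0,
                                      beta_prev_night = 0))
  expect_equal(sd(tr0$target_pnn50), 0)
  expect_lt(abs(cor(tr0$arousal_z, tr0$true_sleep_efficiency)), 0.1)
})

test_that("carry-over induces night-to-night autocorrelation of SE", {
  cfg <- cohort_config(n_participants = 60, n_days = 14, seed = 4,
                       beta_prev_night = 0.5)
  tr <- generate_truth(cfg) |> dplyr::arrange(participant_id, date)
  lg <- qlogis(tr$true_sleep_efficiency)
  prev <- dplyr::lag(lg)
  same <- tr$participant_id == dplyr::lag(tr$participant_id)
  keep <- which(same & !is.na(prev))
  expect_gt(cor(lg[keep], prev[keep]), 0.15)
})

test_that("R-R streams match their closed-form calibration", {
  # zero target with zero jitter gives a constant stream
  st0 <- generate_rri_stream(0, duration = 4, mean_rri = 800, seed = 1)
  expect_true(all(st0$rri_ms == st0$rri_ms[1]))
  expect_equal(pnn50(st0$rri_ms), 0)

  # empirical pNN50 over 50 seeds hits the analytic target
  vals <- vapply(1:50, function(s) {
    pnn50(generate_rri_stream(0.30, duration = 30, mean_rri = 800,
                              seed = s)$rri_ms,
          hrv_config(denominator = "standard"))
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.30), 0.03)

  # sample mean R-R interval close to its nominal value
  st <- generate_rri_stream(0.3, duration = 30, mean_rri = 800, seed = 2)
  expect_lt(abs(mean(st$rri_ms) - 800), 20)
  # timestamps span the requested duration
  span <- as.numeric(max(st$timestamp) - min(st$timestamp), units = "mins")
  expect_gt(span, 29)
  expect_error(generate_rri_stream(1.2, 30, 800, 1),
               class = "sleepcast_domain_error")
  expect_error(generate_rri_stream(0.3, 30, 200, 1),
               class = "sleepcast_domain_error")
})

test_that("missingness injection removes exactly what it reports", {
  rec <- make_recording(hours = 48)
  # zero probabilities: identity
  out0 <- inject_missingness(rec, missingness_config(), seed = 1)
  expect_identical(out0$recording, rec)
  expect_equal(nrow(out0$gaps), 0)

  mc <- missingness_config(p_battery_gap_per_day = 1,
                           battery_gap_minutes = c(40, 40),
                           p_sleeve_occlusion_per_day = 1,
                           occlusion_minutes = c(2, 2))
  out <- inject_missingness(rec, mc, seed = 3)
  expect_true(nrow(out$gaps) >= 2)
  bat <- out$gaps[out$gaps$kind == "battery", ]
  for (g in seq_len(nrow(bat))) {
    sel <- out$recording$timestamp >= bat$start[g] &
      out$recording$timestamp < bat$end[g]
    expect_equal(sum(sel), 0)
  }
  occ <- out$gaps[out$gaps$kind == "occlusion", ]
  for (g in seq_len(nrow(occ))) {
    sel <- out$recording$timestamp >= occ$start[g] &
      out$recording$timestamp < occ$end[g]
    expect_true(all(out$recording$lux[sel] == 0))
    expect_gt(sum(sel), 0) # activity retained during occlusions
  }
})
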