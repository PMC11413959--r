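test_that("all-quiet series scores sleep and huge counts score wake", {
  ep0 <- make_epochs(rep(0, 30))
  expect_true(all(score_epochs(ep0)$sleep))

  ep_big <- make_epochs(rep(1e6, 30))
  expect_true(all(!score_epochs(ep_big)$sleep))
})

test_that("the scorer matches the brute-force weighted sum", {
  set.seed(7)
  for (rep in 1:5) {
    y <- sample(0:2000, 200, TRUE)
    sc <- score_epochs(make_epochs(y))
    expect_equal(sc$score, brute_ck(y), tolerance = 1e-9)
  }
  # parameter identity is recorded
  expect_equal(attr(score_epochs(make_epochs(0)), "ck_param_id"),
               ck_params()$param_id)
})

test_that("raising an epoch's counts never flips it from wake to sleep", {
  set.seed(8)
  y <- sample(0:300, 100, TRUE)
  base <- score_epochs(make_epochs(y))$sleep
  for (t in c(3, 20, 50, 99)) {
    y2 <- y
    y2[t] <- y2[t] + 500
    bumped <- score_epochs(make_epochs(y2))$sleep
    expect_false(!base[t] && bumped[t]) # wake never becomes sleep
  }
})

test_that("sleep-period detection applies the run-length rules", {
  in_bed <- t0("2024-01-01 23:00:00")
  out_bed <- t0("2024-01-02 07:00:00")

  # all-sleep night: onset at in-bed, wake at out-of-bed
  ep <- make_epochs(rep(0, 8 * 60), start = in_bed)
  per <- detect_sleep_period(score_epochs(ep), in_bed, out_bed)
  expect_true(per$scorable)
  expect_equal(per$sleep_onset, in_bed)
  expect_equal(per$wake_time, out_bed)

  # constructed score sequence: wake, wake, then sleep -> SOL of 2 minutes
  sc2 <- make_epochs(rep(0, 480), start = in_bed)
  sc2$score <- 0
  sc2$sleep <- c(FALSE, FALSE, rep(TRUE, 478))
  per2 <- detect_sleep_period(sc2, in_bed, out_bed)
  expect_equal(as.numeric(per2$sleep_onset - in_bed, units = "mins"), 2)

  # only 4-epoch sleep runs (below the default 5): unscorable
  y3 <- rep(c(rep(0, 4), rep(3000, 3)), length.out = 480)
  per3 <- detect_sleep_period(score_epochs(make_epochs(y3, start = in_bed)),
                              in_bed, out_bed)
  expect_false(per3$scorable)
  expect_equal(per3$reason, "no_sleep_run")
})

test_that("nights with too many invalid epochs are dropped with a reason", {
  in_bed <- t0("2024-01-01 23:00:00")
  out_bed <- t0("2024-01-02 07:00:00")
  ep <- make_epochs(rep(0, 480), start = in_bed)
  ep$valid[1:60] <- FALSE # 12.5% > default 10%
  per <- detect_sleep_period(score_epochs(ep), in_bed, out_bed)
  expect_false(per$scorable)
  expect_equal(per$reason, "invalid_epochs")
})

test_that("sleep efficiency uses the inclusive 90% boundary", {
  in_bed <- t0("2024-01-01 23:00:00")
  out_bed <- in_bed + 480 * 60 # TIB 480
  mk <- function(tst) {
    ep <- make_epochs(rep(0, 480), start = in_bed)
    sc <- score_epochs(ep)
    sc$sleep[seq_len(480) > tst] <- FALSE # exactly tst sleep minutes
    sc
  }
  n432 <- compute_sleep_night(mk(432), in_bed, out_bed, in_bed, out_bed)
  expect_equal(n432$sleep_efficiency, 0.90)
  expect_true(n432$good_sleep)

  n431 <- compute_sleep_night(mk(431), in_bed, out_bed, in_bed, out_bed)
  expect_false(n431$good_sleep)
  expect_lt(n431$sleep_efficiency, 0.9)

  full <- compute_sleep_night(mk(480), in_bed, out_bed, in_bed, out_bed)
  expect_equal(full$sleep_efficiency, 1)
  expect_error(compute_sleep_night(mk(480), in_bed, in_bed, in_bed, in_bed),
               class = "sleepcast_invalid_night")
})

test_that("diary-only nights reproduce hand-computed parameters", {
  d <- tibble::tibble(
    participant_id = "P1", date = as.Date("2024-01-01"),
    in_bed = t0("2024-01-01 23:00:00"),
    sleep_onset_latency_min = 20, n_awakenings = 0L,
    wake_time = t0("2024-01-02 07:00:00"),
    out_of_bed = t0("2024-01-02 07:30:00"),
    caffeine = 0L, alcohol = 0L, nap = 0L
  )
  n <- diary_sleep_night(d)
  expect_equal(n$tst_min, 460)
  expect_equal(n$tib_min, 510)
  expect_equal(n$sleep_efficiency, 460 / 510)
  expect_true(n$good_sleep)
  expect_equal(n$source, "diary")

  # SOL 0, no awakenings, onset = in-bed, wake = out-of-bed: SE = 1
  d2 <- d
  d2$sleep_onset_latency_min <- 0
  d2$wake_time <- d2$out_of_bed
  expect_equal(diary_sleep_night(d2)$sleep_efficiency, 1)

  # clock times without rollover: applied when wake < bed
  d3 <- d
  d3$wake_time <- t0("2024-01-01 07:00:00")
  d3$out_of_bed <- t0("2024-01-01 07:30:00")
  expect_equal(diary_sleep_night(d3)$tib_min, 510)

  # irreparably inconsistent times raise a validation error
  d4 <- d
  d4$wake_time <- d4$in_bed - 3 * 86400
  expect_error(diary_sleep_night(d4), class = "sleepcast_validation_error")
})

test_that("scored nights have sane ranges and recover the latent truth", {
  st <- small_study()
  nights <- st$nights[st$nights$scorable, ]
  expect_true(all(nights$sleep_efficiency >= 0 & nights$sleep_efficiency <= 1))
  expect_true(all(nights$waso_min >= 0))
  expect_true(all(nights$sol_min >= 0))
  expect_true(all(nights$tst_min <= nights$tib_min + 1e-9))

  j <- dplyr::inner_join(nights, st$truth, by = c("participant_id", "date"))
  j <- j[j$in_study, ]
  expect_gt(cor(j$sleep_efficiency, j$true_sleep_efficiency), 0.6)
})
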