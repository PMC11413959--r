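test_that("vector magnitude is the Euclidean norm of the axes", {
  expect_equal(vector_magnitude(3, 4, 0), 5)
  expect_equal(vector_magnitude(0, 0, 0), 0)
  expect_error(vector_magnitude(-1, 0, 0), class = "sleepcast_domain_error")

  set.seed(1)
  x <- sample(0:500, 100, TRUE)
  y <- sample(0:500, 100, TRUE)
  z <- sample(0:500, 100, TRUE)
  # independent recomputation, term by term
  expected <- vapply(seq_len(100),
                     function(i) sqrt(sum(c(x[i], y[i], z[i])^2)),
                     numeric(1))
  expect_equal(vector_magnitude(x, y, z), expected, tolerance = 1e-9)
})

test_that("epoch aggregation sums counts and averages lux", {
  rec <- tibble::tibble(
    participant_id = "P1",
    timestamp = t0() + 10 * (0:5),
    axis_x = 0L, axis_y = 1:6, axis_z = 0L,
    lux = c(0, 0, 0, 0, 0, 600)
  )
  ep <- aggregate_epochs(rec)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$y_count, 21)
  expect_equal(ep$vm_count, 21) # x = z = 0 so vm reduces to y
  expect_equal(ep$mean_lux, 100)
  expect_true(ep$valid)
})

test_that("partial and absent epochs are kept but marked invalid", {
  rec <- make_recording(hours = 1)
  # remove 2 samples from the third minute and the whole fifth minute
  drop <- c(13, 14, 25:30)
  rec2 <- rec[-drop, ]
  ep <- aggregate_epochs(rec2)
  expect_equal(nrow(ep), 60) # contiguous grid despite the gap
  expect_equal(ep$n_samples[3], 4L)
  expect_false(ep$valid[3])
  expect_equal(ep$n_samples[5], 0L)
  expect_equal(ep$y_count[5], 0)
  # partition conserves total counts
  expect_equal(sum(ep$y_count), sum(rec2$axis_y))
  # empty input is an empty series, not an error
  expect_equal(nrow(aggregate_epochs(rec[0, ])), 0)
})

test_that("re-aggregating an epoch series is rejected", {
  ep <- aggregate_epochs(make_recording(hours = 1))
  expect_error(aggregate_epochs(ep), class = "sleepcast_domain_error")
})

test_that("activity-gap exclusions trigger at 30 minutes, inclusively", {
  diary <- make_diary2()
  base <- make_recording(hours = 36, start = t0("2024-01-01 00:00:00"))

  cut_minutes <- function(rec, from, minutes) {
    sel <- rec$timestamp >= t0(from) &
      rec$timestamp < t0(from) + minutes * 60
    rec[!sel, ]
  }

  r30 <- cut_minutes(base, "2024-01-01 14:00:00", 30)
  ex30 <- detect_exclusions(r30, diary)
  expect_true(ex30$excluded)
  expect_equal(ex30$reason, "activity_gap_30min")

  r29 <- cut_minutes(base, "2024-01-01 14:00:00", 29)
  ex29 <- detect_exclusions(r29, diary)
  expect_false(ex29$excluded)
  expect_equal(ex29$reason, "none")

  # monotonicity: removing further samples never un-excludes
  r_more <- cut_minutes(r30, "2024-01-01 16:00:00", 10)
  expect_true(detect_exclusions(r_more, diary)$excluded)
})

test_that("zero-lux runs exclude only within the wake span", {
  diary <- make_diary2()
  base <- make_recording(hours = 36, start = t0("2024-01-01 00:00:00"))
  zero_lux <- function(rec, from, minutes) {
    sel <- rec$timestamp >= t0(from) &
      rec$timestamp < t0(from) + minutes * 60
    rec$lux[sel] <- 0
    rec
  }

  day_run <- detect_exclusions(zero_lux(base, "2024-01-01 14:00:00", 3), diary)
  expect_true(day_run$excluded)
  expect_equal(day_run$reason, "lux_gap_3min")

  night_run <- detect_exclusions(zero_lux(base, "2024-01-02 02:00:00", 3),
                                 diary)
  expect_false(night_run$excluded)

  short_run <- detect_exclusions(zero_lux(base, "2024-01-01 14:00:00", 2),
                                 diary)
  expect_false(short_run$excluded)
})

test_that("missing diary anchors mark the unit unresolvable", {
  diary <- make_diary2()
  diary$in_bed[2] <- NA
  ex <- detect_exclusions(make_recording(hours = 36), diary)
  expect_true(ex$excluded)
  expect_equal(ex$reason, "unresolvable")
})
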