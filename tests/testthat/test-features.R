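test_that("window partition follows the four-window day layout", {
  w <- partition_windows(as.Date("2024-01-02"),
                         t0("2024-01-02 07:30:00"),
                         t0("2024-01-02 23:30:00"),
                         t0("2024-01-03 07:30:00"))
  len_h <- as.numeric(w$end - w$start, units = "hours")
  expect_equal(w$window, c("morning", "afternoon", "evening", "sleep"))
  expect_equal(len_h, c(4.5, 6, 5.5, 8))

  # out-of-bed after noon: empty morning, shortened afternoon
  w2 <- partition_windows(as.Date("2024-01-02"),
                          t0("2024-01-02 12:30:00"),
                          t0("2024-01-02 23:30:00"),
                          t0("2024-01-03 07:30:00"))
  expect_lte(as.numeric(w2$end[1] - w2$start[1]), 0)
  expect_equal(as.numeric(w2$end[2] - w2$start[2], units = "hours"), 5.5)

  # in-bed before 18:00: empty evening
  w3 <- partition_windows(as.Date("2024-01-02"),
                          t0("2024-01-02 07:30:00"),
                          t0("2024-01-02 17:00:00"),
                          t0("2024-01-03 05:00:00"))
  expect_lte(as.numeric(w3$end[3] - w3$start[3]), 0)

  expect_error(partition_windows(as.Date("2024-01-02"),
                                 t0("2024-01-03 00:30:00"),
                                 t0("2024-01-02 23:30:00"),
                                 t0("2024-01-03 07:30:00")),
               class = "sleepcast_validation_error")
})

test_that("window features match independent recomputation", {
  ep <- make_epochs(rep(100, 60), lux = 0)
  ep$vm_count <- 100
  f <- extract_window_features(ep, ep$epoch_start[1],
                               ep$epoch_start[60] + 60)
  expect_equal(f$vm_mean, 100)
  expect_equal(f$vm_sd, 0)
  expect_equal(f$vm_max, 100)
  expect_equal(f$lux_mean, 0)
  expect_equal(f$loglux_mean, 0)

  set.seed(9)
  ep2 <- make_epochs(sample(0:900, 120, TRUE),
                     lux = 0)
  ep2$vm_count <- runif(120, 0, 1200)
  ep2$mean_lux <- runif(120, 0, 2000)
  spec <- feature_spec()
  f2 <- extract_window_features(ep2, ep2$epoch_start[1],
                                ep2$epoch_start[120] + 60, spec)
  vm <- ep2$vm_count
  lx <- ep2$mean_lux
  expect_equal(f2$vm_mean, sum(vm) / 120)
  expect_equal(f2$vm_sd, sqrt(sum((vm - mean(vm))^2) / 119))
  expect_equal(f2$vm_p90, unname(quantile(vm, 0.9)))
  expect_equal(f2$frac_active, mean(vm >= spec$moderate_vm))
  expect_equal(f2$lux_mean, mean(lx))
  expect_equal(f2$loglux_mean, mean(log10(1 + lx)))
  expect_equal(f2$frac_bright, mean(lx >= spec$bright_lux))
})

test_that("windows with under half their epochs valid are all-missing", {
  ep <- make_epochs(rep(100, 60))
  ep$valid[1:31] <- FALSE
  f <- extract_window_features(ep, ep$epoch_start[1],
                               ep$epoch_start[60] + 60)
  expect_true(all(is.na(unlist(f))))
  # empty span likewise
  f0 <- extract_window_features(ep, ep$epoch_start[1], ep$epoch_start[1])
  expect_true(all(is.na(unlist(f0))))
})

test_that("the k-day assembler emits exactly D - k + 1 units when all valid", {
  st <- small_study()
  du <- st$day_units
  du$valid <- TRUE
  du$night_good <- !is.na(du$night_good) & du$night_good
  per <- dplyr::count(du, participant_id)
  for (k in 1:3) {
    u <- assemble_units(du, k, source = "combined", hrv_included = FALSE)
    expect_equal(nrow(u), sum(per$n - k + 1))
  }
  expect_error(assemble_units(du, 4L, "combined"),
               class = "sleepcast_domain_error")
})

test_that("an invalid middle day breaks unit consecutiveness", {
  st <- small_study()
  du <- st$day_units[st$day_units$participant_id == "P001", ][1:5, ]
  du$valid <- TRUE
  du$night_good <- TRUE
  du$valid[3] <- FALSE
  u <- assemble_units(du, 2, source = "combined", hrv_included = FALSE)
  expect_equal(nrow(u), 2)
  expect_equal(as.numeric(u$date), as.numeric(du$date[c(2, 5)]))
})

test_that("predictors never contain the final night's outcome", {
  st <- small_study()
  u2 <- assemble_units(st$day_units, 2, source = "combined",
                       hrv_included = FALSE)
  nm <- names(u2)
  # the final day's night-outcome and sleep-window features must be absent
  expect_false(any(grepl("^d2_night_", nm)))
  expect_false(any(grepl("^d2_sleep_", nm)))
  expect_false(any(grepl("^d2_diary_(sol|awak|tib)", nm)))
  # but the prior day's are present
  expect_true("d1_night_se" %in% nm)
  expect_true("d1_sleep_vm_mean" %in% nm)
  expect_true("d1_diary_sol" %in% nm)
  # 1-day units carry no night-derived predictors at all
  u1 <- assemble_units(st$day_units, 1, source = "combined",
                       hrv_included = FALSE)
  expect_false(any(grepl("night_|sleep_|diary_", names(u1))))
})

test_that("zeroing the final night's recording changes no predictor", {
  st <- small_study()
  target <- st$day_units$date[which(st$day_units$valid)[5]]
  pid <- st$day_units$participant_id[which(st$day_units$valid)[5]]
  diary_row <- st$diary[st$diary$participant_id == pid &
                          st$diary$date == target, ]

  epochs2 <- st$epochs[st$epochs$participant_id == pid, ]
  sel <- epochs2$epoch_start >= diary_row$in_bed &
    epochs2$epoch_start < diary_row$out_of_bed
  epochs2$y_count[sel] <- 0
  epochs2$vm_count[sel] <- 0
  epochs2$mean_lux[sel] <- 0

  diary_p <- st$diary[st$diary$participant_id == pid, ]
  nights_p <- score_nights(epochs2, diary_p)
  hrv_p <- st$hrv[st$hrv$participant_id == pid, ]
  excl_p <- st$exclusions[st$exclusions$participant_id == pid, ]
  du2 <- build_day_units(epochs2, diary_p, nights_p, hrv_p, excl_p)

  du1 <- st$day_units[st$day_units$participant_id == pid, ]
  for (k in 1:2) {
    a <- assemble_units(du1, k, "combined", hrv_included = FALSE)
    b <- assemble_units(du2, k, "combined", hrv_included = FALSE)
    ia <- which(a$date == target)
    ib <- which(b$date == target)
    expect_equal(length(ia), 1)
    expect_equal(length(ib), 1)
    drop <- c("seq", "label")
    expect_equal(tibble::as_tibble(a[ia, setdiff(names(a), drop)]),
                 tibble::as_tibble(b[ib, setdiff(names(b), drop)]))
    expect_equal(a$seq[[ia]], b$seq[[ib]])
  }
})

test_that("identical inputs give identical feature tables", {
  st <- small_study()
  a <- assemble_units(st$day_units, 2, "combined", hrv_included = TRUE)
  b <- assemble_units(st$day_units, 2, "combined", hrv_included = TRUE)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("sources drop the right feature families", {
  st <- small_study()
  dev <- assemble_units(st$day_units, 2, "device", hrv_included = TRUE)
  expect_false(any(grepl("caffeine|alcohol|nap|diary_", names(dev))))
  expect_true(any(grepl("pnn50", names(dev))))

  dia <- assemble_units(st$day_units, 2, "diary", hrv_included = TRUE)
  expect_false(any(grepl("vm_|lux|pnn50", names(dia))))
  expect_true(all(c("d2_caffeine", "d1_diary_sol") %in% names(dia)))
  # diary units carry no device sequences
  expect_true(all(vapply(dia$seq, function(m) all(m == 0), logical(1))))
})
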