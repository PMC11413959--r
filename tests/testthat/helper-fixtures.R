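# Shared fixture builders.  Everything is generated in code; no data files.

t0 <- function(x = "2024-01-01 00:00:00") as.POSIXct(x, tz = "UTC")

# epoch tibble from a y-count vector (valid, zero lux unless given)
make_epochs <- function(y, start = t0(), pid = "P1", lux = 0,
                        valid = TRUE) {
  n <- length(y)
  tibble::tibble(
    participant_id = pid,
    epoch_start = start + 60 * (seq_len(n) - 1),
    y_count = as.numeric(y),
    vm_count = as.numeric(y) * 1.2,
    mean_lux = rep_len(as.numeric(lux), n),
    n_samples = 6L,
    valid = rep_len(valid, n)
  )
}

# complete 10-s raw recording over [start, start + hours) with constant or
# per-sample values
make_recording <- function(hours = 24, start = t0(), pid = "P1",
                           y = 10L, lux = 100) {
  n <- as.integer(hours * 360)
  tibble::tibble(
    participant_id = pid,
    timestamp = start + 10 * (seq_len(n) - 1),
    axis_x = rep_len(as.integer(y * 0.6), n),
    axis_y = rep_len(as.integer(y), n),
    axis_z = rep_len(as.integer(y * 0.5), n),
    lux = rep_len(as.numeric(lux), n)
  )
}

# two-night diary (one scored unit on the middle date) with clean anchors
make_diary2 <- function(pid = "P1",
                        oob1 = "2024-01-01 07:30:00",
                        bed2 = "2024-01-01 23:00:00",
                        oob2 = "2024-01-02 07:30:00") {
  tibble::tibble(
    participant_id = pid,
    date = as.Date(c("2023-12-31", "2024-01-01")),
    in_bed = c(t0("2023-12-31 23:00:00"), t0(bed2)),
    sleep_onset_latency_min = c(10, 10),
    n_awakenings = c(0L, 0L),
    sleep_time = c(t0("2023-12-31 23:10:00"), t0(bed2) + 600),
    wake_time = c(t0(oob1) - 300, t0(oob2) - 300),
    out_of_bed = c(t0(oob1), t0(oob2)),
    caffeine = 0L, alcohol = 0L, nap = 0L
  )
}

# a small coupled study, cached per test file run
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_study(cohort_config(n_participants = 4, n_days = 8,
                                          seed = 42), keep_epochs = TRUE)
    }
    cache
  }
})

# brute-force scorer oracle: literal weighted sum at every epoch
brute_ck <- function(y, params = ck_params()) {
  n <- length(y)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (i in -4:2) {
      j <- t + i
      a <- if (j >= 1 && j <= n) y[j] else 0
      acc <- acc + params$weights[i + 5] * a / params$count_divisor
    }
    out[t] <- params$scale * acc
  }
  out
}

# brute-force pNN50 under both conventions
brute_pnn50 <- function(r, literal = TRUE, thr = 50) {
  cnt <- 0
  for (i in seq_len(length(r) - 1)) {
    if (abs(r[i + 1] - r[i]) > thr) cnt <- cnt + 1
  }
  cnt / (if (literal) length(r) else length(r) - 1)
}
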