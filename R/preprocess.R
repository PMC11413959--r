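#' Vector magnitude of triaxial activity counts
#'
#' Euclidean norm \eqn{\sqrt{x^2 + y^2 + z^2}} of the three axis counts;
#' vectorised.
#'
#' @param x,y,z Nonnegative activity counts.
#' @return Numeric vector of magnitudes.
#' @export
#' @examples
#' vector_magnitude(3, 4, 0)
vector_magnitude <- function(x, y, z) {
  if (any(c(x, y, z) < 0, na.rm = TRUE)) {
    abort("activity counts must be nonnegative",
          class = "sleepcast_domain_error", field = "x/y/z")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Aggregate a 10-second recording to 60-second epochs
#'
#' Each 60-second epoch (half-open, aligned to the midnight-anchored minute
#' grid) holds the sum of its six 10-second y-axis counts and vector
#' magnitudes and the mean of the six lux values.  Epochs with fewer than six
#' samples are kept with the statistics of the available samples but marked
#' invalid; epochs with no samples at all (device gaps) appear with zero
#' counts, `n_samples = 0` and `valid = FALSE`, so the returned series is
#' contiguous from the first to the last observed epoch.
#'
#' @param recording Tibble with `participant_id, timestamp, axis_x, axis_y,
#'   axis_z, lux`.  Re-aggregating an epoch series is rejected.
#' @param config A [preprocess_config()]; `activity_stat = "sum"` (default,
#'   the counts-per-epoch actigraphy convention) or `"mean"`.
#'
#' @return Tibble with `participant_id, epoch_start, y_count, vm_count,
#'   mean_lux, n_samples, valid`.
#' @export
aggregate_epochs <- function(recording, config = preprocess_config()) {
  if (any(c("vm_count", "y_count", "epoch_start") %in% names(recording))) {
    abort("`recording` looks already aggregated; re-aggregation is not allowed",
          class = "sleepcast_domain_error", field = "recording")
  }
  need <- c("participant_id", "timestamp", "axis_x", "axis_y", "axis_z", "lux")
  sc_assert(all(need %in% names(recording)),
            paste("`recording` must have columns:", paste(need, collapse = ", ")),
            field = "recording")
  if (nrow(recording) == 0) {
    return(tibble(participant_id = character(), epoch_start = sc_time(character()),
                  y_count = numeric(), vm_count = numeric(),
                  mean_lux = numeric(), n_samples = integer(),
                  valid = logical()))
  }
  ep <- config$epoch_seconds

  parts <- split(seq_len(nrow(recording)), recording$participant_id)
  res <- purrr::imap(parts, function(rows, pid) {
    tsec <- as.numeric(recording$timestamp[rows])
    vm <- vector_magnitude(recording$axis_x[rows], recording$axis_y[rows],
                           recording$axis_z[rows])
    y <- as.numeric(recording$axis_y[rows])
    lux <- recording$lux[rows]
    e0 <- floor(min(tsec) / ep)
    idx <- floor(tsec / ep) - e0 + 1
    n_ep <- floor(max(tsec) / ep) - e0 + 1
    # grouped sums on the contiguous epoch grid (absent epochs stay zero)
    acc <- rowsum(cbind(y = y, vm = vm,
                        lux = ifelse(is.na(lux), 0, lux),
                        lux_n = as.numeric(!is.na(lux)),
                        n = 1),
                  idx, reorder = TRUE)
    at <- as.integer(rownames(acc))
    n_samples <- integer(n_ep)
    n_samples[at] <- as.integer(acc[, "n"])
    y_sum <- numeric(n_ep)
    y_sum[at] <- acc[, "y"]
    vm_sum <- numeric(n_ep)
    vm_sum[at] <- acc[, "vm"]
    lux_sum <- numeric(n_ep)
    lux_sum[at] <- acc[, "lux"]
    lux_n <- numeric(n_ep)
    lux_n[at] <- acc[, "lux_n"]
    mean_lux <- ifelse(lux_n > 0, lux_sum / lux_n, NA_real_)
    if (config$activity_stat == "mean") {
      y_sum <- ifelse(n_samples > 0, y_sum / n_samples, 0)
      vm_sum <- ifelse(n_samples > 0, vm_sum / n_samples, 0)
    }
    tibble(
      participant_id = pid,
      epoch_start = sc_time((e0 + seq_len(n_ep) - 1) * ep),
      y_count = y_sum, vm_count = vm_sum, mean_lux = mean_lux,
      n_samples = n_samples, valid = n_samples == 6L
    )
  })
  bind_rows(res)
}

# merge possibly-overlapping intervals given as two numeric vectors (seconds)
sc_merge_intervals <- function(start, end, join_gap = 0) {
  if (!length(start)) {
    return(list(start = numeric(), end = numeric()))
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  outs <- numeric()
  oute <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + join_gap) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms)
      oute <- c(oute, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  list(start = c(outs, ms), end = c(oute, me))
}

# total overlap length (seconds) of intervals with window [w0, w1); also the
# longest single run inside the window
sc_runs_in_window <- function(iv, w0, w1) {
  if (!length(iv$start)) {
    return(tibble(start = numeric(), end = numeric(), len = numeric()))
  }
  s <- pmax(iv$start, w0)
  e <- pmin(iv$end, w1)
  keep <- e > s
  tibble(start = s[keep], end = e[keep], len = e[keep] - s[keep])
}

#' Detect missing-data exclusions per day-night unit
#'
#' Applies the two exclusion rules of the processing protocol: a unit is
#' excluded if activity samples are absent for a continuous run of at least
#' `activity_gap_min` minutes (default 30) anywhere in the day-night unit, or
#' if lux is zero-or-absent for a continuous run of at least `lux_gap_min`
#' minutes (default 3) during the wake span (out-of-bed to in-bed).
#' Comparisons are inclusive: a run of exactly 30:00 (or 3:00) excludes.
#' Absent samples -- not zero counts -- define activity non-measurement, since
#' genuine stillness and battery depletion cannot be separated from counts
#' alone.  The light rule looks at recorded samples whose lux reading is zero
#' or absent (sensor occlusion); whole-sample gaps are the activity rule's
#' business.  Zero lux counts only while the participant is out of bed,
#' because darkness during sleep is expected.
#'
#' The unit for diary date `D` spans from the previous night's out-of-bed
#' time (morning of `D`) to the current night's out-of-bed time (morning of
#' `D + 1`); its wake span runs to the current night's in-bed time.  The
#' first diary row per participant anchors the first unit's morning and does
#' not itself form a unit.
#'
#' @param recording Raw recording tibble (see [aggregate_epochs()]).
#' @param diary Diary tibble with `participant_id, date, in_bed, out_of_bed`
#'   (datetimes).
#' @param config A [preprocess_config()].
#'
#' @return Tibble with one row per participant-unit: `participant_id, date,
#'   excluded, reason` (one of `activity_gap_30min`, `lux_gap_3min`,
#'   `unresolvable`, `none`) and list-columns `activity_gap_runs`,
#'   `lux_zero_runs` holding the detected runs.
#' @export
detect_exclusions <- function(recording, diary, config = preprocess_config()) {
  sc_assert(all(c("participant_id", "date", "in_bed", "out_of_bed") %in%
                  names(diary)),
            "`diary` must have participant_id, date, in_bed, out_of_bed",
            field = "diary")
  diary <- diary %>% arrange(.data$participant_id, .data$date)

  per_part <- split(recording, recording$participant_id)
  empty_runs <- tibble(start = numeric(), end = numeric(), len = numeric())

  out <- diary %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(function(dd, key) {
      pid <- key$participant_id
      rec <- per_part[[pid]]
      if (is.null(rec) || nrow(rec) == 0) {
        return(tibble(date = dd$date[-1], excluded = TRUE,
                      reason = "unresolvable",
                      activity_gap_runs = list(empty_runs),
                      lux_zero_runs = list(empty_runs)))
      }
      ts <- sort(as.numeric(rec$timestamp))
      # absent-sample gaps: between consecutive samples and at the recording
      # edges each sample covers [t, t + 10)
      dgap <- which(diff(ts) > 10)
      gap_iv <- list(start = ts[dgap] + 10, end = ts[dgap + 1])
      # zero-or-absent lux on recorded samples only: whole-sample gaps count
      # toward the activity rule, not the light rule
      zl <- is.na(rec$lux) | rec$lux == 0
      zts <- as.numeric(rec$timestamp)[zl]
      lux_iv <- sc_merge_intervals(zts, zts + 10)
      rec_lo <- ts[1]
      rec_hi <- ts[length(ts)] + 10

      rows <- purrr::map(seq_len(nrow(dd))[-1], function(i) {
        anchors <- c(dd$out_of_bed[i - 1], dd$in_bed[i], dd$out_of_bed[i])
        if (any(is.na(anchors))) {
          return(tibble(date = dd$date[i], excluded = TRUE,
                        reason = "unresolvable",
                        activity_gap_runs = list(empty_runs),
                        lux_zero_runs = list(empty_runs)))
        }
        u0 <- as.numeric(dd$out_of_bed[i - 1])
        w1 <- as.numeric(dd$in_bed[i])
        u1 <- as.numeric(dd$out_of_bed[i])
        # recording edges count as absence if they cut into the unit
        edge_iv <- list(start = c(-Inf, rec_hi), end = c(rec_lo, Inf))
        act_iv <- sc_merge_intervals(c(gap_iv$start, edge_iv$start),
                                     c(gap_iv$end, edge_iv$end))
        act_runs <- sc_runs_in_window(act_iv, u0, u1)
        lux_runs <- sc_runs_in_window(lux_iv, u0, w1)
        act_hit <- any(act_runs$len >= config$activity_gap_min * 60)
        lux_hit <- any(lux_runs$len >= config$lux_gap_min * 60)
        tibble(
          date = dd$date[i],
          excluded = act_hit || lux_hit,
          reason = if (act_hit) "activity_gap_30min"
                   else if (lux_hit) "lux_gap_3min" else "none",
          activity_gap_runs = list(act_runs),
          lux_zero_runs = list(lux_runs)
        )
      })
      bind_rows(rows)
    }) %>%
    ungroup()
  out
}
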