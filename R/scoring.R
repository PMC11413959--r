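#' Score 60-second epochs sleep/wake (Cole-Kripke style)
#'
#' For each epoch the weighted moving-window score
#' \eqn{D_t = P \sum_{i=-4}^{+2} w_i\, a_{t+i}/c} is computed over the y-axis
#' counts, with zero padding outside the series; the epoch is scored sleep
#' when \eqn{D_t <} `sleep_threshold`.  Invalid epochs keep their partial
#' counts in the weighted sum but are forced to wake in the output (tracked
#' via `valid`), a conservative treatment of device gaps inside the night.
#'
#' @param epochs Epoch tibble from [aggregate_epochs()] (any number of
#'   participants; each participant's series must be contiguous, which
#'   [aggregate_epochs()] guarantees).
#' @param params A [ck_params()].
#'
#' @return The input with `score` and `sleep` columns appended; the scoring
#'   parameter identity is recorded in attribute `ck_param_id`.
#' @export
#' @examples
#' ep <- tibble::tibble(participant_id = "P1",
#'   epoch_start = sleepcast:::sc_time("2024-01-01 00:00:00") + 60 * (0:9),
#'   y_count = rep(0, 10), vm_count = 0, mean_lux = 0,
#'   n_samples = 6L, valid = TRUE)
#' all(score_epochs(ep)$sleep)
score_epochs <- function(epochs, params = ck_params()) {
  if (nrow(epochs) == 0) {
    out <- epochs
    out$score <- numeric(0)
    out$sleep <- logical(0)
    return(out)
  }
  out <- epochs %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(function(df, key) {
      df$score <- sc_ck_score(df$y_count, params)
      df$sleep <- df$score < params$sleep_threshold & df$valid
      df
    }) %>%
    ungroup()
  attr(out, "ck_param_id") <- params$param_id
  out
}

# weighted moving window with zero padding; offsets -4..+2
sc_ck_score <- function(y, params) {
  n <- length(y)
  ypad <- c(rep(0, 4), y / params$count_divisor, rep(0, 2))
  acc <- numeric(n)
  for (k in 0:6) {
    acc <- acc + params$weights[k + 1] * ypad[seq_len(n) + k]
  }
  params$scale * acc
}

#' Detect the sleep period within a diary-anchored night
#'
#' Sleep onset is the start of the first run of at least
#' `onset_run_length` consecutive sleep-scored epochs at or after the diary
#' in-bed time; the final wake time is the end of the last run of at least
#' `offset_run_length` consecutive sleep epochs at or before the diary
#' out-of-bed time.  Nights without a qualifying run, or whose invalid-epoch
#' fraction inside the in-bed span exceeds `max_invalid_fraction`, are
#' flagged unscorable with a reason.
#'
#' @param scored One participant's scored epochs ([score_epochs()] output).
#' @param in_bed,out_of_bed POSIXct diary anchors bracketing the night.
#' @param params A [ck_params()].
#'
#' @return List with `sleep_onset`, `wake_time` (POSIXct or NA), `scorable`,
#'   `reason` (`"ok"`, `"no_sleep_run"`, `"invalid_epochs"`, `"no_epochs"`).
#' @export
detect_sleep_period <- function(scored, in_bed, out_of_bed,
                                params = ck_params()) {
  sel <- scored$epoch_start < out_of_bed &
    scored$epoch_start + 60 > in_bed
  night <- scored[sel, ]
  na_out <- list(sleep_onset = sc_time(NA_real_), wake_time = sc_time(NA_real_),
                 scorable = FALSE, reason = "no_epochs")
  if (nrow(night) == 0) {
    return(na_out)
  }
  if (mean(!night$valid) > params$max_invalid_fraction) {
    na_out$reason <- "invalid_epochs"
    return(na_out)
  }
  r <- rle(night$sleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  qual_on <- r$values & r$lengths >= params$onset_run_length
  qual_off <- r$values & r$lengths >= params$offset_run_length
  if (!any(qual_on) || !any(qual_off)) {
    na_out$reason <- "no_sleep_run"
    return(na_out)
  }
  first_run <- which(qual_on)[1]
  last_run <- tail(which(qual_off), 1)
  onset <- max(night$epoch_start[starts[first_run]], in_bed)
  wake <- min(night$epoch_start[ends[last_run]] + 60, out_of_bed)
  if (wake <= onset) {
    na_out$reason <- "no_sleep_run"
    return(na_out)
  }
  list(sleep_onset = onset, wake_time = wake, scorable = TRUE, reason = "ok")
}

#' Sleep parameters and the good-sleep label for one night
#'
#' Total sleep time is the count of sleep-scored epoch minutes in
#' `[sleep_onset, wake_time)`; wake after sleep onset is the remainder of
#' that span; time in bed runs from in-bed to out-of-bed; sleep efficiency is
#' TST / TIB.  The good-sleep boundary is inclusive: SE of exactly 0.90 is
#' labelled good.
#'
#' @param scored One participant's scored epochs.
#' @param in_bed,out_of_bed POSIXct diary anchors.
#' @param sleep_onset,wake_time Detected sleep period
#'   ([detect_sleep_period()]).
#'
#' @return One-row tibble with `in_bed, sleep_onset, wake_time, out_of_bed,
#'   sol_min, waso_min, tst_min, tib_min, sleep_efficiency, good_sleep`.
#' @export
compute_sleep_night <- function(scored, in_bed, out_of_bed,
                                sleep_onset, wake_time) {
  tib_min <- as.numeric(out_of_bed - in_bed, units = "mins")
  if (!is.finite(tib_min) || tib_min <= 0) {
    abort("time in bed must be positive", class = "sleepcast_invalid_night",
          field = "in_bed/out_of_bed")
  }
  sel <- scored$epoch_start >= sleep_onset & scored$epoch_start < wake_time
  tst_min <- sum(scored$sleep[sel])
  span_min <- as.numeric(wake_time - sleep_onset, units = "mins")
  waso_min <- max(0, span_min - tst_min)
  sol_min <- as.numeric(sleep_onset - in_bed, units = "mins")
  se <- min(1, tst_min / tib_min)
  tibble(
    in_bed = in_bed, sleep_onset = sleep_onset, wake_time = wake_time,
    out_of_bed = out_of_bed, sol_min = sol_min, waso_min = waso_min,
    tst_min = tst_min, tib_min = tib_min,
    sleep_efficiency = se, good_sleep = se >= 0.90
  )
}

#' Score all diary-anchored nights of a cohort
#'
#' Runs [score_epochs()], then for every unit night (each diary row from the
#' second onwards per participant) detects the sleep period and computes the
#' night's sleep parameters.  Unscorable nights are kept with
#' `scorable = FALSE` and a reason, never silently dropped.
#'
#' @param epochs Epoch tibble ([aggregate_epochs()]).
#' @param diary Diary tibble with datetimes `in_bed`, `out_of_bed` and `date`.
#' @param params A [ck_params()].
#'
#' @return Tibble, one row per participant-night: diary `date`, sleep
#'   parameters, `sleep_efficiency`, `good_sleep`, `scorable`, `reason`,
#'   `source = "device"` and the scoring `param_id`.
#' @export
score_nights <- function(epochs, diary, params = ck_params()) {
  scored <- score_epochs(epochs, params)
  scored_by <- split(scored, scored$participant_id)
  diary <- diary %>% arrange(.data$participant_id, .data$date)

  diary %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(function(dd, key) {
      sc <- scored_by[[key$participant_id]]
      rows <- purrr::map(seq_len(nrow(dd)), function(i) {
        base <- tibble(
          date = dd$date[i], in_bed = dd$in_bed[i],
          sleep_onset = sc_time(NA_real_), wake_time = sc_time(NA_real_),
          out_of_bed = dd$out_of_bed[i], sol_min = NA_real_,
          waso_min = NA_real_, tst_min = NA_real_,
          tib_min = as.numeric(dd$out_of_bed[i] - dd$in_bed[i],
                               units = "mins"),
          sleep_efficiency = NA_real_, good_sleep = NA,
          scorable = FALSE, reason = "no_epochs"
        )
        if (is.null(sc)) {
          return(base)
        }
        per <- detect_sleep_period(sc, dd$in_bed[i], dd$out_of_bed[i], params)
        if (!per$scorable) {
          base$reason <- per$reason
          return(base)
        }
        nt <- compute_sleep_night(sc, dd$in_bed[i], dd$out_of_bed[i],
                                  per$sleep_onset, per$wake_time)
        nt$date <- dd$date[i]
        nt$scorable <- TRUE
        nt$reason <- "ok"
        nt[, names(base)]
      })
      bind_rows(rows)
    }) %>%
    ungroup() %>%
    mutate(source = "device", param_id = params$param_id)
}

#' Sleep parameters from the diary alone
#'
#' Builds a diary-sourced sleep night per row: onset is in-bed plus the
#' reported sleep-onset latency; total sleep time is the onset-to-wake span
#' minus reported awakening time (the number of awakenings times a default
#' bout length when awakening minutes are not recorded).  A date rollover is
#' applied when a reported clock time precedes the previous field.
#'
#' @param diary Diary tibble with `participant_id, date, in_bed,
#'   sleep_onset_latency_min, n_awakenings, wake_time, out_of_bed` and the
#'   `caffeine, alcohol, nap` flags.
#' @param awakening_bout_min Assumed minutes per reported awakening.
#'
#' @return Tibble in the same shape as [score_nights()], `source = "diary"`.
#' @export
#' @examples
#' d <- tibble::tibble(participant_id = "P1", date = as.Date("2024-01-01"),
#'   in_bed = sleepcast:::sc_time("2024-01-01 23:00:00"),
#'   sleep_onset_latency_min = 20, n_awakenings = 0,
#'   wake_time = sleepcast:::sc_time("2024-01-02 07:00:00"),
#'   out_of_bed = sleepcast:::sc_time("2024-01-02 07:30:00"))
#' diary_sleep_night(d)$sleep_efficiency
diary_sleep_night <- function(diary, awakening_bout_min = 5) {
  d <- diary
  roll <- function(later, earlier) {
    later + ifelse(later < earlier, 86400, 0)
  }
  d$wake_time <- roll(d$wake_time, d$in_bed)
  d$out_of_bed <- roll(d$out_of_bed, d$wake_time)
  bad <- which(d$out_of_bed < d$wake_time | d$wake_time < d$in_bed)
  if (length(bad)) {
    abort(paste0("inconsistent diary times (wake before bed) in rows: ",
                 paste(head(bad, 5), collapse = ", "),
                 "; offending fields: in_bed/wake_time"),
          class = "sleepcast_validation_error", field = "wake_time")
  }
  d %>%
    mutate(
      sol_min = .data$sleep_onset_latency_min,
      sleep_onset = .data$in_bed + .data$sol_min * 60,
      waso_min = .data$n_awakenings * awakening_bout_min,
      tst_min = pmax(0, as.numeric(.data$wake_time - .data$sleep_onset,
                                   units = "mins") - .data$waso_min),
      tib_min = as.numeric(.data$out_of_bed - .data$in_bed, units = "mins"),
      sleep_efficiency = pmin(1, .data$tst_min / .data$tib_min),
      good_sleep = .data$sleep_efficiency >= 0.90,
      scorable = TRUE, reason = "ok", source = "diary"
    ) %>%
    select(all_of(c("participant_id", "date", "in_bed", "sleep_onset",
                    "wake_time", "out_of_bed", "sol_min", "waso_min",
                    "tst_min", "tib_min", "sleep_efficiency", "good_sleep",
                    "scorable", "reason", "source")))
}
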