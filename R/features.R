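#' Feature specification (version tag and thresholds)
#'
#' Declares the per-window summary statistics computed by the feature
#' builder: mean, SD, max and 90th percentile of the epoch vector-magnitude
#' counts; the fraction of epochs above a moderate-activity threshold; mean
#' lux; mean \eqn{\log_{10}(1 + lux)}; and the fraction of epochs at or above
#' a bright-light threshold.  Statistics use valid epochs only and are all
#' missing when fewer than `min_valid_frac` of a window's epochs are valid.
#' An identical spec implies identical feature names and ordering.
#'
#' @param version Version tag recorded with every feature table.
#' @param moderate_vm Vector-magnitude counts/epoch at or above which an
#'   epoch counts as moderate activity.
#' @param bright_lux Lux level at or above which an epoch counts as bright.
#' @param min_valid_frac Minimum valid fraction of a window's epochs.
#' @param seq_steps Steps per window for the fixed-grid sequence channels
#'   (\eqn{\log(1+vm)}, \eqn{\log_{10}(1+lux)}) consumed by the neural
#'   learners.
#'
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(version = "v1", moderate_vm = 500,
                         bright_lux = 1000, min_valid_frac = 0.5,
                         seq_steps = 16L) {
  structure(
    list(version = version, moderate_vm = moderate_vm,
         bright_lux = bright_lux, min_valid_frac = min_valid_frac,
         seq_steps = as.integer(seq_steps)),
    class = "feature_spec"
  )
}

sc_window_stats <- c("vm_mean", "vm_sd", "vm_max", "vm_p90", "frac_active",
                     "lux_mean", "loglux_mean", "frac_bright")

#' Partition one day-night unit into its four windows
#'
#' Morning runs from the previous night's out-of-bed time to noon, afternoon
#' from noon to 18:00, evening from 18:00 to the night's in-bed time, and
#' sleep from in-bed to the next morning's out-of-bed time; all half-open.
#' An out-of-bed time after noon yields an empty morning window and an
#' in-bed time before 18:00 an empty evening window (empty windows produce
#' missing features, not zeros).
#'
#' @param date Unit (calendar) date.
#' @param out_of_bed_prev POSIXct rise time on the morning of `date`.
#' @param in_bed POSIXct in-bed time of the unit's night.
#' @param out_of_bed POSIXct rise time ending the unit's night.
#'
#' @return Tibble with `window`, `start`, `end` (empty windows have
#'   `end <= start`).
#' @export
#' @examples
#' partition_windows(as.Date("2024-01-02"),
#'   sleepcast:::sc_time("2024-01-02 07:30:00"),
#'   sleepcast:::sc_time("2024-01-02 23:30:00"),
#'   sleepcast:::sc_time("2024-01-03 07:30:00"))
partition_windows <- function(date, out_of_bed_prev, in_bed, out_of_bed) {
  if (out_of_bed_prev >= in_bed) {
    abort("out-of-bed time is not before the same night's in-bed time",
          class = "sleepcast_validation_error", field = "out_of_bed_prev")
  }
  noon <- sc_time(paste(date, "12:00:00"))
  six_pm <- sc_time(paste(date, "18:00:00"))
  tibble(
    window = c("morning", "afternoon", "evening", "sleep"),
    start = c(out_of_bed_prev, max(noon, out_of_bed_prev), six_pm, in_bed),
    end = c(min(noon, in_bed), min(six_pm, in_bed), in_bed, out_of_bed)
  )
}

#' Summary features of an epoch span
#'
#' Computes the [feature_spec()] statistics over the valid epochs of
#' `epochs` whose `epoch_start` lies in `[start, end)`.  Returns all-missing
#' features for an empty span or when fewer than `min_valid_frac` of the
#' span's epochs are valid.
#'
#' @param epochs Epoch tibble (one participant).
#' @param start,end POSIXct span bounds (minute-aligned).
#' @param spec A [feature_spec()].
#'
#' @return One-row tibble with the eight window statistics.
#' @export
extract_window_features <- function(epochs, start, end,
                                    spec = feature_spec()) {
  expected <- max(0, floor(as.numeric(end - start, units = "mins")))
  sel <- epochs$epoch_start >= start & epochs$epoch_start < end
  ep <- epochs[sel & epochs$valid, ]
  sc_span_features(ep$vm_count, ep$mean_lux, expected, spec)
}

sc_span_features <- function(vm, lux, expected, spec) {
  if (expected == 0 || length(vm) < spec$min_valid_frac * expected) {
    return(as_tibble(setNames(as.list(rep(NA_real_, length(sc_window_stats))),
                              sc_window_stats)))
  }
  lux <- ifelse(is.na(lux), 0, lux)
  tibble(
    vm_mean = mean(vm), vm_sd = if (length(vm) > 1) sd(vm) else 0,
    vm_max = max(vm), vm_p90 = unname(quantile(vm, 0.9, type = 7)),
    frac_active = mean(vm >= spec$moderate_vm),
    lux_mean = mean(lux), loglux_mean = mean(log10(1 + lux)),
    frac_bright = mean(lux >= spec$bright_lux)
  )
}

# resample a window's epoch channels to a fixed-length grid; invalid epochs
# are interpolated over, fully-missing windows become zeros
sc_resample_seq <- function(vm, lux, valid, steps) {
  out <- matrix(0, nrow = steps, ncol = 2)
  n <- length(vm)
  if (n == 0 || !any(valid)) {
    return(out)
  }
  xi <- seq(1, n, length.out = steps)
  v <- log1p(vm)
  l <- log10(1 + ifelse(is.na(lux), 0, lux))
  if (!all(valid)) {
    idx <- which(valid)
    v <- stats::approx(idx, v[idx], xout = seq_len(n), rule = 2)$y
    l <- stats::approx(idx, l[idx], xout = seq_len(n), rule = 2)$y
  }
  if (n == 1) {
    out[, 1] <- v
    out[, 2] <- l
  } else {
    out[, 1] <- stats::approx(seq_len(n), v, xout = xi)$y
    out[, 2] <- stats::approx(seq_len(n), l, xout = xi)$y
  }
  out
}

#' Build per-day analysis units for a cohort
#'
#' Joins the epoch series, diary, scored nights, nightly HRV and exclusion
#' report into one row per participant-day unit: device features for the
#' four windows, the previous night's diary recall (sleep-onset latency,
#' awakenings, time in bed), the day's behaviour flags, the pre-sleep pNN50
#' of the unit's night, the scored night parameters, and the good-sleep
#' label.  A unit is valid when it is not excluded by the missing-data rules
#' and its night is scorable.
#'
#' @param epochs Epoch tibble ([aggregate_epochs()]).
#' @param diary Diary tibble (datetimes).
#' @param nights Device-scored nights ([score_nights()]).
#' @param hrv Nightly HRV summaries ([hrv_nightly()]), or `NULL`.
#' @param exclusions Exclusion report ([detect_exclusions()]), or `NULL` for
#'   a gap-free cohort.
#' @param spec A [feature_spec()].
#'
#' @return Tibble of day units, one row per participant-date, with a `seq`
#'   list-column holding the per-window fixed-grid sequence channels.
#' @export
build_day_units <- function(epochs, diary, nights, hrv = NULL,
                            exclusions = NULL, spec = feature_spec()) {
  diary <- diary %>% arrange(.data$participant_id, .data$date)

  units <- diary %>%
    group_by(.data$participant_id) %>%
    mutate(out_of_bed_prev = lag(.data$out_of_bed)) %>%
    ungroup() %>%
    filter(!is.na(.data$out_of_bed_prev)) %>%
    mutate(
      # the unit's own night as reported in the diary: a night-outcome
      # feature, usable only for the non-final days of a k-day unit
      diary_sol = .data$sleep_onset_latency_min,
      diary_awak = as.numeric(.data$n_awakenings),
      diary_tib = as.numeric(.data$out_of_bed - .data$in_bed, units = "mins")
    )

  bad <- units$out_of_bed_prev >= units$in_bed
  if (any(bad)) {
    abort("out-of-bed time at or after the same night's in-bed time",
          class = "sleepcast_validation_error", field = "out_of_bed_prev")
  }

  # window span table, one row per unit-window
  spans <- bind_rows(
    units %>% mutate(window = "morning",
                     start = .data$out_of_bed_prev,
                     end = pmin(sc_time(paste(.data$date, "12:00:00")),
                                .data$in_bed)),
    units %>% mutate(window = "afternoon",
                     start = pmax(sc_time(paste(.data$date, "12:00:00")),
                                  .data$out_of_bed_prev),
                     end = pmin(sc_time(paste(.data$date, "18:00:00")),
                                .data$in_bed)),
    units %>% mutate(window = "evening",
                     start = sc_time(paste(.data$date, "18:00:00")),
                     end = .data$in_bed),
    units %>% mutate(window = "sleep",
                     start = .data$in_bed, end = .data$out_of_bed)
  ) %>%
    select(all_of(c("participant_id", "date", "window", "start", "end"))) %>%
    filter(.data$end > .data$start)

  joined <- dplyr::inner_join(
    epochs, spans,
    by = join_by("participant_id", "epoch_start" >= "start",
                 "epoch_start" < "end")
  )

  wf <- joined %>%
    group_by(.data$participant_id, .data$date, .data$window) %>%
    summarise(
      stats = list(sc_span_features(
        .data$vm_count[.data$valid],
        .data$mean_lux[.data$valid],
        expected = floor(as.numeric(.data$end[1] - .data$start[1],
                                    units = "mins")),
        spec = spec
      )),
      seq = list(sc_resample_seq(.data$vm_count, .data$mean_lux,
                                 .data$valid, spec$seq_steps)),
      .groups = "drop"
    ) %>%
    tidyr::unnest("stats")

  # wide: dev_<window>_<stat> columns + per-window seq list
  wf_wide <- wf %>%
    tidyr::pivot_wider(
      id_cols = c("participant_id", "date"),
      names_from = "window",
      values_from = c(all_of(sc_window_stats), "seq"),
      names_glue = "{window}_{.value}"
    )
  # ensure all window columns exist even if a window is empty cohort-wide
  for (w in c("morning", "afternoon", "evening", "sleep")) {
    for (s in sc_window_stats) {
      cn <- paste0(w, "_", s)
      if (!cn %in% names(wf_wide)) wf_wide[[cn]] <- NA_real_
    }
    cn <- paste0(w, "_seq")
    if (!cn %in% names(wf_wide)) {
      wf_wide[[cn]] <- list(matrix(0, spec$seq_steps, 2))
    }
  }
  zero_seq <- matrix(0, spec$seq_steps, 2)
  for (w in c("morning", "afternoon", "evening", "sleep")) {
    cn <- paste0(w, "_seq")
    wf_wide[[cn]] <- purrr::map(wf_wide[[cn]], ~ .x %||% zero_seq)
  }

  nights_sel <- nights %>%
    select(all_of(c("participant_id", "date", "sol_min", "waso_min",
                    "tst_min", "sleep_efficiency", "good_sleep",
                    "scorable")))
  out <- units %>%
    select(all_of(c("participant_id", "date", "caffeine", "alcohol", "nap",
                    "diary_sol", "diary_awak", "diary_tib"))) %>%
    left_join(wf_wide, by = c("participant_id", "date")) %>%
    left_join(nights_sel, by = c("participant_id", "date")) %>%
    rename(night_sol = "sol_min", night_waso = "waso_min",
           night_tst = "tst_min", night_se = "sleep_efficiency",
           night_good = "good_sleep")

  if (!is.null(hrv)) {
    out <- out %>%
      left_join(hrv %>% select(all_of(c("participant_id", "date",
                                        "pnn50_presleep"))),
                by = c("participant_id", "date"))
  } else {
    out$pnn50_presleep <- NA_real_
  }

  if (!is.null(exclusions)) {
    out <- out %>%
      left_join(exclusions %>% select(all_of(c("participant_id", "date",
                                               "excluded", "reason"))),
                by = c("participant_id", "date")) %>%
      mutate(excluded = dplyr::coalesce(.data$excluded, FALSE))
  } else {
    out$excluded <- FALSE
    out$reason <- "none"
  }

  out %>%
    mutate(
      scorable = dplyr::coalesce(.data$scorable, FALSE),
      valid = !.data$excluded & .data$scorable
    ) %>%
    mutate(spec_version = spec$version)
}

# day-level column groups used by the assembler
sc_day_cols_dev <- function() {
  as.vector(outer(c("morning", "afternoon", "evening"), sc_window_stats,
                  paste, sep = "_"))
}
sc_night_cols_dev <- function() {
  c(paste0("sleep_", sc_window_stats),
    "night_sol", "night_waso", "night_tst", "night_se")
}
sc_night_cols_diary <- function() c("diary_sol", "diary_awak", "diary_tib")
sc_flag_cols <- function() c("caffeine", "alcohol", "nap")

#' Assemble k-day prediction units
#'
#' Slides a window of `k` consecutive calendar dates over each participant's
#' day units and emits one prediction unit per window in which all `k` days
#' are valid (and, when `hrv_included`, have a non-missing pre-sleep pNN50).
#' The label is the final night's good-sleep flag.  Predictors never include
#' the final night's sleep-window or night-outcome features: the final day
#' contributes its morning/afternoon/evening device features, behaviour
#' flags and pre-sleep pNN50 only, while days `1..k-1` additionally
#' contribute their sleep-window device features, scored-night parameters
#' and diary-reported night values.  Thus only units with `k >= 2` carry any
#' information about earlier nights' sleep.  `source = "device"` drops diary
#' features, `source = "diary"` drops device and HRV features, `"combined"`
#' keeps all.
#'
#' Feature columns are prefixed `d1_` (oldest) .. `dk_` (final day); the
#' sequence list-column concatenates each day's window grids (plus prior
#' nights' sleep grids) in temporal order.
#'
#' @param day_units Day-unit tibble ([build_day_units()]).
#' @param k Days per unit (1, 2 or 3).
#' @param source `"device"`, `"diary"` or `"combined"`.
#' @param hrv_included Include pre-sleep pNN50 scalars (device and combined
#'   sources only).
#'
#' @return Tibble of class `feature_units`: `participant_id, date` (final
#'   day), feature columns, `seq` list-column, and logical `label` last.
#' @export
assemble_units <- function(day_units, k,
                           source = c("combined", "device", "diary"),
                           hrv_included = FALSE) {
  source <- match.arg(source)
  if (!k %in% 1:3) {
    abort("`k` must be 1, 2 or 3", class = "sleepcast_domain_error",
          field = "k")
  }
  du <- day_units %>% arrange(.data$participant_id, .data$date)

  use_dev <- source %in% c("device", "combined")
  use_diary <- source %in% c("diary", "combined")
  use_hrv <- hrv_included && use_dev

  final_cols <- c(if (use_dev) sc_day_cols_dev(),
                  if (use_diary) sc_flag_cols(),
                  if (use_hrv) "pnn50_presleep")
  prior_cols <- c(final_cols,
                  if (use_dev) sc_night_cols_dev(),
                  if (use_diary) sc_night_cols_diary())

  n <- nrow(du)
  ok_lag <- function(l) {
    # TRUE where the row l days back is the same participant, l days earlier,
    # and valid (and HRV-complete when required)
    if (l == 0) {
      ok <- du$valid
    } else {
      ok <- du$participant_id == lag(du$participant_id, l) &
        as.numeric(du$date - lag(du$date, l)) == l &
        lag(du$valid, l)
      ok[is.na(ok)] <- FALSE
    }
    if (use_hrv) {
      p <- if (l == 0) du$pnn50_presleep else lag(du$pnn50_presleep, l)
      ok <- ok & !is.na(p)
    }
    ok
  }
  eligible <- Reduce(`&`, lapply(0:(k - 1), ok_lag))
  eligible <- eligible & !is.na(du$night_good)
  idx <- which(eligible)

  lag_cols <- function(cols, l, prefix) {
    m <- du[, cols, drop = FALSE]
    if (l > 0) {
      m <- dplyr::mutate(m, across(dplyr::everything(), ~ lag(.x, l)))
    }
    m <- m[idx, , drop = FALSE]
    names(m) <- paste0(prefix, "_", names(m))
    m
  }

  parts <- list(
    du[idx, c("participant_id", "date")]
  )
  for (j in seq_len(k)) {
    l <- k - j # lag from the final day
    cols <- if (j < k) prior_cols else final_cols
    parts[[length(parts) + 1]] <- lag_cols(cols, l, paste0("d", j))
  }
  feats <- dplyr::bind_cols(parts)
  feats <- dplyr::mutate(feats, across(-all_of(c("participant_id", "date")),
                                       as.numeric))

  # concatenated sequence grids in temporal order; the sequence channels are
  # device data, so the diary source gets all-zero grids of the same shape
  seq_cols <- paste0(c("morning", "afternoon", "evening", "sleep"), "_seq")
  seqs <- purrr::map(idx, function(i) {
    blocks <- list()
    for (j in seq_len(k)) {
      row <- i - (k - j)
      wins <- if (j < k) seq_cols else seq_cols[1:3]
      for (w in wins) blocks[[length(blocks) + 1]] <- du[[w]][[row]]
    }
    out <- do.call(rbind, blocks)
    if (!use_dev) out[] <- 0
    out
  })
  feats$seq <- seqs
  feats$label <- du$night_good[idx]

  structure(feats,
            class = c("feature_units", class(tibble())),
            k = k, source = source, hrv_included = hrv_included,
            spec_version = du$spec_version[1] %||% "v1")
}
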