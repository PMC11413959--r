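#' Generate a synthetic wearable-sleep cohort
#'
#' Produces, for every participant, a complete multi-day recording of
#' 10-second triaxial activity counts and illuminance, nightly pre-sleep R-R
#' interval streams, daily sleep-diary entries, and the latent truth table
#' (arousal state, true sleep efficiency, true good-sleep label, true
#' bed/rise times).  The generator implements the dependence structure the
#' downstream analysis assumes: a smooth circadian activity profile scaled by
#' a participant amplitude, evening activity and late light raised by a
#' latent nightly arousal state, pre-sleep pNN50 lowered by the same arousal
#' state, first-order night-to-night carry-over of logit sleep efficiency,
#' and diary reporting noise.  Night-time wake is realised as movement bouts
#' whose total duration equals \eqn{(1 - SE) \cdot TIB}, so actigraphy
#' scoring of the generated night recovers a sleep efficiency close to the
#' latent truth by construction.
#'
#' With `n_days` recording days there are `n_days - 1` full nights inside the
#' recording (13 prediction units for the default 14 days); the diary also
#' carries one extra row for the night preceding day 1, whose morning rise
#' anchors the first day's windows.
#'
#' @param config A [cohort_config()].
#'
#' @return A list of class `sleepcast_cohort` with elements
#'   `recordings` (tibble: `participant_id, timestamp, axis_x, axis_y,
#'   axis_z, lux`), `rri` (tibble: `participant_id, date, timestamp,
#'   rri_ms`), `diary` (one row per participant-night), `truth` (latent truth,
#'   one row per participant-night), `gaps` (injected-missingness log) and
#'   `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 1, n_days = 3, seed = 1))
#' dplyr::count(coh$diary, participant_id)
generate_cohort <- function(config) {
  sc_assert(inherits(config, "cohort_config"),
            "`config` must be a cohort_config()", field = "config")
  truth <- sc_cohort_truth(config)
  mc <- config$missingness
  inject <- mc$p_battery_gap_per_day > 0 || mc$p_sleeve_occlusion_per_day > 0
  gap_list <- list()
  recs <- purrr::map(seq_len(config$n_participants), function(i) {
    pid <- truth$profiles$participant_id[i]
    nights_i <- truth$nights[truth$nights$participant_id == pid, ]
    rec <- sc_participant_recording(truth$profiles[i, ], nights_i, config)
    if (inject) {
      inj <- inject_missingness(rec, mc,
                                seed = derive_seed(config$seed,
                                                   paste0("miss-", pid)))
      gap_list[[pid]] <<- inj$gaps
      rec <- inj$recording
    }
    rec
  })
  recordings <- bind_rows(recs)

  rri <- sc_cohort_rri(truth, config)
  diary <- sc_cohort_diary(truth$nights)

  gaps <- if (length(gap_list)) {
    bind_rows(gap_list)
  } else {
    tibble(participant_id = character(), kind = character(),
           start = sc_time(character()), end = sc_time(character()))
  }

  truth_tbl <- truth$nights %>%
    select(all_of(c("participant_id", "date", "in_study", "arousal_z",
                    "true_sleep_efficiency", "true_good_sleep",
                    "true_in_bed", "true_sleep_onset", "true_wake",
                    "true_out_of_bed", "target_pnn50")))

  structure(
    list(recordings = recordings, rri = rri, diary = diary,
         truth = truth_tbl, gaps = gaps, config = config,
         nights_detail = truth$nights, profiles = truth$profiles),
    class = "sleepcast_cohort"
  )
}

#' @export
print.sleepcast_cohort <- function(x, ...) {
  cat("<sleepcast_cohort>\n")
  cat("  participants:", x$config$n_participants,
      " days:", x$config$n_days, "\n")
  cat("  recording rows:", nrow(x$recordings),
      " rri rows:", nrow(x$rri), "\n")
  cat("  marginal good-sleep rate (in-study nights):",
      round(mean(x$truth$true_good_sleep[x$truth$in_study]), 3), "\n")
  invisible(x)
}

#' Generate only the latent truth of a cohort
#'
#' Runs the structural model (arousal, covariates, calibrated logit-linear
#' sleep efficiency with night-to-night carry-over) without synthesising the
#' activity, lux or R-R streams.  Useful for calibration checks at large
#' cohort sizes.
#'
#' @param config A [cohort_config()].
#' @return Tibble, one row per participant-night, with `in_study`,
#'   `arousal_z`, `true_sleep_efficiency`, `true_good_sleep`, true times and
#'   `target_pnn50`.
#' @export
#' @examples
#' tr <- generate_truth(cohort_config(n_participants = 5, seed = 1))
#' mean(tr$true_good_sleep[tr$in_study])
generate_truth <- function(config) {
  sc_assert(inherits(config, "cohort_config"),
            "`config` must be a cohort_config()", field = "config")
  sc_cohort_truth(config)$nights %>%
    select(all_of(c("participant_id", "date", "in_study", "arousal_z",
                    "true_sleep_efficiency", "true_good_sleep",
                    "true_in_bed", "true_sleep_onset", "true_wake",
                    "true_out_of_bed", "target_pnn50")))
}

# ---- latent truth ----------------------------------------------------------

# Participant-level profiles: circadian amplitude, chronotype, lux habits,
# resting mean R-R interval.
sc_cohort_profiles <- function(config) {
  n <- config$n_participants
  tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    amp = stats::rlnorm(n, log(130), 0.25),
    bed_mean_min = pmin(pmax(rnorm(n, 23.5 * 60, 45), 22 * 60), 25.5 * 60),
    rise_mean_min = pmin(pmax(rnorm(n, 7.5 * 60, 45), 5.5 * 60), 10 * 60),
    lux_day = stats::rlnorm(n, log(300), 0.4),
    mean_rri = runif(n, 700, 950)
  )
}

# One row per participant-night.  Night j (j = -1 .. n_days - 2) has evening
# date start_date + j and rises on the following morning; j = -1 is the night
# before the first recording day (only its morning lies inside the recording).
sc_cohort_truth <- function(config) {
  with_seed(derive_seed(config$seed, "truth"), {
    profiles <- sc_cohort_profiles(config)
    start_date <- as.Date("2024-01-01")

    nights <- tidyr::expand_grid(
      participant_id = profiles$participant_id,
      j = seq(-1L, config$n_days - 2L)
    ) %>%
      left_join(profiles, by = "participant_id") %>%
      mutate(
        date = start_date + .data$j,
        in_study = .data$j >= 0L,
        arousal_z = rnorm(n()),
        # nightly jitter around the chronotype; clamp TIB to [5h, 11h]
        bed_min = .data$bed_mean_min + rnorm(n(), 0, 20),
        rise_min = .data$rise_mean_min + rnorm(n(), 0, 20),
        # evening indoor illuminance level for the night (lux)
        lux_evening = stats::rlnorm(n(), log(80), 0.5)
      ) %>%
      mutate(
        rise_min = pmin(pmax(.data$rise_min,
                             .data$bed_min - 1440 + 5 * 60),
                        .data$bed_min - 1440 + 11 * 60) + 1440
      )
    # rise_min is minutes from the evening date's midnight (so > 1440)

    # scalar structural covariates, standardized by their analytic moments
    gamma_ev <- 0.2
    a_ev <- nights$amp * (1 + gamma_ev * nights$arousal_z)
    mu_amp <- 130 * exp(0.25^2 / 2)
    m2_amp <- 130^2 * exp(2 * 0.25^2)
    mu_a <- mu_amp
    sd_a <- sqrt(m2_amp * (1 + gamma_ev^2) - mu_amp^2)
    mu_l <- 80 * exp(0.5^2 / 2)
    sd_l <- sqrt(80^2 * (exp(0.5^2) - 1) * exp(0.5^2))
    nights$cov_evening_activity <- (a_ev - mu_a) / sd_a
    nights$cov_late_light <- (nights$lux_evening - mu_l) / sd_l

    eps <- rnorm(nrow(nights), 0, config$noise_sd)
    xb <- config$beta_arousal * nights$arousal_z +
      config$beta_evening_activity * nights$cov_evening_activity +
      config$beta_late_light * nights$cov_late_light

    bp <- config$beta_prev_night
    recurse_logit <- function(beta0) {
      out <- numeric(nrow(nights))
      idx <- split(seq_len(nrow(nights)), nights$participant_id)
      for (ii in idx) {
        prev <- beta0 / (1 - bp) # stationary level for the initial night
        for (k in ii) {
          lg <- beta0 + bp * prev + xb[k] + eps[k]
          out[k] <- lg
          prev <- lg
        }
      }
      out
    }

    beta0 <- config$beta0 %||% NULL
    if (is.null(beta0)) {
      in_study <- nights$in_study
      f <- function(b0) {
        mean(plogis(recurse_logit(b0))[in_study] >= 0.90) -
          config$prevalence_target
      }
      beta0 <- uniroot(f, lower = -15, upper = 15, tol = 1e-4,
                       extendInt = "upX")$root
    }
    nights$logit_se <- recurse_logit(beta0)
    nights$true_sleep_efficiency <- plogis(nights$logit_se)
    nights$true_good_sleep <- nights$true_sleep_efficiency >= 0.90
    nights$target_pnn50 <- plogis(qlogis(config$pnn50_base) +
                                    config$beta_arousal * nights$arousal_z)

    # realise the night's wake budget as SOL + WASO bouts + terminal wake
    nights <- nights %>%
      mutate(
        tib_min = round(.data$rise_min - .data$bed_min),
        wake_min = pmin(round((1 - .data$true_sleep_efficiency) *
                                .data$tib_min),
                        .data$tib_min - 30),
        sol_min = pmax(0, round(0.3 * .data$wake_min)),
        term_min = pmax(0, round(0.1 * .data$wake_min)),
        waso_min = pmax(0, .data$wake_min - .data$sol_min - .data$term_min)
      )
    nights$waso_bouts <- purrr::pmap(
      list(nights$waso_min, nights$sol_min, nights$term_min, nights$tib_min),
      sc_place_waso_bouts
    )

    # diary reporting: iid noise plus an arousal-proportional shift
    shift <- config$diary_arousal_shift_min * nights$arousal_z
    nights <- nights %>%
      mutate(
        rep_bed_min = round(.data$bed_min + shift +
                              rnorm(n(), 0, config$diary_noise_sd_min)),
        rep_rise_min = round(.data$rise_min + shift +
                               rnorm(n(), 0, config$diary_noise_sd_min)),
        rep_sol_min = pmax(0, round(.data$sol_min + rnorm(n(), 0, 5))),
        rep_term_min = pmax(0, round(.data$term_min + rnorm(n(), 0, 3))),
        n_awakenings = pmax(0, purrr::map_int(.data$waso_bouts, nrow) +
                              sample(c(-1L, 0L, 0L, 0L, 1L), n(),
                                     replace = TRUE)),
        caffeine = rbinom(n(), 1, plogis(-1 + 0.5 * .data$arousal_z)),
        alcohol = rbinom(n(), 1, plogis(-1.8 + 0.3 * .data$arousal_z)),
        nap = rbinom(n(), 1, 0.15)
      ) %>%
      mutate(rep_rise_min = pmax(.data$rep_rise_min, .data$rep_bed_min + 60))

    midnight <- sc_time(paste(nights$date, "00:00:00"))
    nights <- nights %>%
      mutate(
        true_in_bed = midnight + .data$bed_min * 60,
        true_sleep_onset = midnight + (.data$bed_min + .data$sol_min) * 60,
        true_wake = midnight + (.data$rise_min - .data$term_min) * 60,
        true_out_of_bed = midnight + .data$rise_min * 60,
        rep_in_bed = midnight + .data$rep_bed_min * 60,
        rep_out_of_bed = midnight + .data$rep_rise_min * 60
      )

    list(profiles = profiles, nights = nights, beta0 = beta0,
         start_date = start_date)
  })
}

# place WASO bouts (2-6 min) uniformly in the sleep span, avoiding the onset
# and terminal runs; returns tibble(start_min, dur_min) relative to in-bed
sc_place_waso_bouts <- function(waso_min, sol_min, term_min, tib_min) {
  if (waso_min <= 0) {
    return(tibble(start_min = numeric(), dur_min = numeric()))
  }
  lo <- sol_min + 6
  hi <- tib_min - term_min - 6
  starts <- numeric()
  durs <- numeric()
  remaining <- waso_min
  guard <- 0
  while (remaining > 0 && guard < 100) {
    guard <- guard + 1
    dur <- min(remaining, sample(2:6, 1))
    if (hi - dur <= lo) {
      # night too packed; extend the last bout instead
      if (length(durs)) durs[length(durs)] <- durs[length(durs)] + remaining
      break
    }
    ok <- FALSE
    for (try in 1:10) {
      s <- floor(runif(1, lo, hi - dur))
      if (!length(starts) ||
          all(s + dur + 1 < starts | starts + durs + 1 < s)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) next
    starts <- c(starts, s)
    durs <- c(durs, dur)
    remaining <- remaining - dur
  }
  o <- order(starts)
  tibble(start_min = starts[o], dur_min = durs[o])
}

# ---- streams ---------------------------------------------------------------

# Smooth circadian daytime shape over clock hour; peaks mid-afternoon.
sc_circadian_shape <- function(hour) {
  pmax(0, sin(pi * (hour - 6.5) / 17.5))
}

# Daylight illuminance bell over clock hour (before indoor attenuation).
sc_daylight_shape <- function(hour) {
  exp(-((hour - 13) / 4.5)^2) * as.numeric(hour > 5.5 & hour < 20.5)
}

# Build one participant's complete 10-second recording from the latent truth.
sc_participant_recording <- function(profile, nights, config) {
  with_seed(derive_seed(config$seed, paste0("rec-", profile$participant_id)), {
    # first recording day: the j = -1 night's date is the day before day 1
    origin <- sc_time(paste(min(nights$date) + 1L, "00:00:00"))
    n_samp <- config$n_days * 8640L
    t_off <- (seq_len(n_samp) - 1) * 10
    ts <- origin + t_off
    hour <- (t_off %% 86400) / 3600
    lambda <- rep(0.03, n_samp) # resting/sleep baseline (per 10-s y counts)
    lux <- numeric(n_samp)

    sec_of <- function(x) as.numeric(x - origin, units = "secs")
    idx_span <- function(a, b) {
      # half-open [a, b) on the 10-s grid, clipped to the recording
      lo <- max(0, ceiling(sec_of(a) / 10))
      hi <- min(n_samp, ceiling(sec_of(b) / 10))
      if (hi <= lo) integer() else seq.int(lo + 1L, hi)
    }

    # per-sample y rate during in-bed wake bouts; identical to the waking
    # floor so that in-bed wakefulness is indistinguishable in magnitude
    # from quiet evening wakefulness (only its position carries information)
    lam_wake_bout <- 55

    nights <- nights[order(nights$date), ]
    for (k in seq_len(nrow(nights))) {
      nt <- nights[k, ]
      # in-bed span (clipped): sleep baseline then wake bouts
      bed <- nt$true_in_bed
      rise <- nt$true_out_of_bed
      ib <- idx_span(bed, rise)
      if (length(ib)) lambda[ib] <- 0.03
      if (nt$sol_min > 0) {
        s <- idx_span(bed, bed + nt$sol_min * 60)
        lambda[s] <- lam_wake_bout
      }
      bouts <- nt$waso_bouts[[1]]
      if (nrow(bouts)) {
        for (b in seq_len(nrow(bouts))) {
          s <- idx_span(bed + bouts$start_min[b] * 60,
                        bed + (bouts$start_min[b] + bouts$dur_min[b]) * 60)
          lambda[s] <- lam_wake_bout
        }
      }
      # terminal wake
      if (nt$term_min > 0) {
        s <- idx_span(rise - nt$term_min * 60, rise)
        lambda[s] <- lam_wake_bout
      }
      # bedside light until lights-off; dawn light before rise
      lights_off <- max(nt$true_sleep_onset, bed + 20 * 60)
      s <- idx_span(bed, min(lights_off, rise))
      if (length(s)) lux[s] <- 5
      dawn_on <- rise - max(nt$term_min, 15) * 60
      s <- idx_span(max(dawn_on, bed), rise)
      if (length(s)) lux[s] <- 5
    }

    # daytime wake spans: rise of night j -> bed of night j+1 (same day)
    for (k in seq_len(nrow(nights))) {
      rise <- nights$true_out_of_bed[k]
      bed_next <- if (k < nrow(nights)) {
        nights$true_in_bed[k + 1]
      } else {
        # nominal final evening: chronotype bed time on the last day
        sc_time(paste(nights$date[k] + 1, "00:00:00")) +
          profile$bed_mean_min * 60
      }
      z_next <- if (k < nrow(nights)) nights$arousal_z[k + 1] else 0
      lux_ev <- if (k < nrow(nights)) nights$lux_evening[k + 1] else 80
      s <- idx_span(rise, bed_next)
      if (!length(s)) next
      h <- hour[s]
      ev_factor <- ifelse(h >= 18 | h < 4,
                          pmax(0.1, 1 + 0.2 * z_next), 1)
      # slow within-day modulation (30-min blocks); the floor keeps quiet
      # wakefulness above the scorer's sleep threshold, so sleep/wake status
      # is driven by the latent night structure rather than by daytime lulls
      block <- (s - s[1]) %/% 180
      mod <- stats::rlnorm(max(block) + 1, 0, 0.3)[block + 1]
      lambda[s] <- pmax(55, profile$amp * sc_circadian_shape(h) * ev_factor * mod)
      lux[s] <- pmax(3, profile$lux_day * sc_daylight_shape(h) +
                       lux_ev * as.numeric(h >= 18 | h < 4))
    }

    # sample the streams
    ax <- rpois(n_samp, 0.6 * lambda)
    ay <- rpois(n_samp, lambda)
    az <- rpois(n_samp, 0.5 * lambda)
    lux_out <- ifelse(lux > 0, lux * stats::rlnorm(n_samp, 0, 0.5), 0)

    tibble(participant_id = profile$participant_id, timestamp = ts,
           axis_x = ax, axis_y = ay, axis_z = az, lux = round(lux_out, 1))
  })
}

# Nightly pre-sleep R-R streams for all in-study nights.
sc_cohort_rri <- function(truth, config) {
  nights <- truth$nights[truth$nights$in_study, ]
  purrr::pmap(
    list(nights$participant_id, as.character(nights$date),
         nights$target_pnn50, nights$true_in_bed,
         nights$mean_rri, seq_len(nrow(nights))),
    function(pid, date, target, in_bed, mean_rri, k) {
      st <- generate_rri_stream(
        target_pnn50 = target, duration = 30, mean_rri = mean_rri,
        seed = derive_seed(config$seed, paste0("rri-", pid, "-", date)),
        start = in_bed - 30 * 60
      )
      tibble(participant_id = pid, date = as.Date(date),
             timestamp = st$timestamp, rri_ms = st$rri_ms)
    }
  ) %>% bind_rows()
}

sc_cohort_diary <- function(nights) {
  nights %>%
    mutate(
      sleep_time = .data$rep_in_bed + .data$rep_sol_min * 60,
      wake_time = .data$rep_out_of_bed - .data$rep_term_min * 60
    ) %>%
    transmute(
      participant_id = .data$participant_id,
      date = .data$date,
      in_bed = .data$rep_in_bed,
      sleep_onset_latency_min = .data$rep_sol_min,
      n_awakenings = .data$n_awakenings,
      sleep_time = .data$sleep_time,
      wake_time = .data$wake_time,
      out_of_bed = .data$rep_out_of_bed,
      caffeine = .data$caffeine,
      alcohol = .data$alcohol,
      nap = .data$nap
    )
}

#' @importFrom dplyr transmute
NULL

# ---- R-R stream generator --------------------------------------------------

#' Generate a pre-sleep R-R interval stream with a target pNN50
#'
#' R-R intervals are drawn as independent Gaussian deviations around
#' `mean_rri`.  Successive differences are then marginally
#' \eqn{N(0, \sigma_d^2)}, and the jitter scale is solved in closed form from
#' the Gaussian tail so that \eqn{P(|d| > 50\,\mathrm{ms}) = }
#' `target_pnn50`: \eqn{\sigma_d = 50 / \Phi^{-1}(1 - p/2)}, with per-beat
#' deviation SD \eqn{\sigma_d / \sqrt{2}}.  `target_pnn50 = 0` yields a
#' constant stream.
#'
#' @param target_pnn50 Desired expected pNN50, in `[0, 1)`.
#' @param duration Stream duration in minutes (>= 2).
#' @param mean_rri Mean R-R interval in ms, in `[400, 1500]`.
#' @param seed Integer seed.
#' @param start POSIXct start time of the stream.
#'
#' @return Tibble with `timestamp` and `rri_ms`; timestamps span `duration`.
#' @export
#' @examples
#' st <- generate_rri_stream(0.3, duration = 4, mean_rri = 800, seed = 1)
#' pnn50(st$rri_ms)
generate_rri_stream <- function(target_pnn50, duration, mean_rri, seed,
                                start = sc_time("2000-01-01 00:00:00")) {
  if (!is.numeric(target_pnn50) || target_pnn50 < 0 || target_pnn50 >= 1) {
    abort("`target_pnn50` must lie in [0, 1)",
          class = "sleepcast_domain_error", field = "target_pnn50")
  }
  sc_assert(duration >= 2, "`duration` must be at least 2 minutes",
            field = "duration", class = "sleepcast_domain_error")
  sc_assert(mean_rri >= 400 && mean_rri <= 1500,
            "`mean_rri` must lie in [400, 1500] ms",
            field = "mean_rri", class = "sleepcast_domain_error")
  with_seed(seed, {
    sigma_d <- if (target_pnn50 == 0) 0 else 50 / qnorm(1 - target_pnn50 / 2)
    sigma <- sigma_d / sqrt(2)
    n <- ceiling(duration * 60000 / mean_rri)
    rri <- mean_rri + rnorm(n, 0, sigma)
    rri <- pmax(rri, 250) # physical floor; essentially never binds
    tt <- start + cumsum(rri) / 1000
    keep <- as.numeric(tt - start, units = "secs") <= duration * 60 + 1
    tibble(timestamp = tt[keep], rri_ms = rri[keep])
  })
}

# ---- missingness injection -------------------------------------------------

#' Inject device missingness into a complete recording
#'
#' Battery gaps remove both activity and lux samples over the gap; sleeve
#' occlusions set lux to zero during the daytime but keep activity.  The
#' returned gap log records the ground truth so downstream exclusion logic
#' can be verified against it.
#'
#' @param recording Tibble in raw-recording form (`participant_id, timestamp,
#'   axis_x, axis_y, axis_z, lux`), gap-free.
#' @param config A [missingness_config()].
#' @param seed Integer seed.
#'
#' @return List with `recording` (rows removed / lux zeroed) and `gaps`
#'   (tibble: `participant_id, kind, start, end`).
#' @export
inject_missingness <- function(recording, config, seed) {
  sc_assert(inherits(config, "missingness_config"),
            "`config` must be a missingness_config()", field = "config")
  with_seed(seed, {
    days <- recording %>%
      mutate(day = as.Date(.data$timestamp)) %>%
      distinct(.data$participant_id, .data$day)
    gaps <- purrr::pmap(
      list(days$participant_id, as.character(days$day)),
      function(pid, day) {
        out <- list()
        if (runif(1) < config$p_battery_gap_per_day) {
          dur <- runif(1, config$battery_gap_minutes[1],
                       config$battery_gap_minutes[2])
          s0 <- runif(1, 0, 24 * 60 - dur)
          out$battery <- tibble(
            participant_id = pid, kind = "battery",
            start = sc_time(paste(day, "00:00:00")) + s0 * 60,
            end = sc_time(paste(day, "00:00:00")) + (s0 + dur) * 60
          )
        }
        if (runif(1) < config$p_sleeve_occlusion_per_day) {
          dur <- runif(1, config$occlusion_minutes[1],
                       config$occlusion_minutes[2])
          s0 <- runif(1, 9 * 60, 17 * 60 - dur)
          out$occ <- tibble(
            participant_id = pid, kind = "occlusion",
            start = sc_time(paste(day, "00:00:00")) + s0 * 60,
            end = sc_time(paste(day, "00:00:00")) + (s0 + dur) * 60
          )
        }
        bind_rows(out)
      }
    ) %>% bind_rows()

    if (nrow(gaps)) {
      for (g in seq_len(nrow(gaps))) {
        sel <- recording$participant_id == gaps$participant_id[g] &
          recording$timestamp >= gaps$start[g] &
          recording$timestamp < gaps$end[g]
        if (gaps$kind[g] == "battery") {
          recording <- recording[!sel, ]
        } else {
          recording$lux[sel] <- 0
        }
      }
    }
    list(recording = recording, gaps = gaps)
  })
}
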