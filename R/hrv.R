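#' pNN50 of an R-R interval sequence
#'
#' Counts successive-difference magnitudes strictly greater than 50 ms after
#' physiological gating (intervals outside `rri_gate_ms` dropped; successive
#' differences larger than `max_successive_diff_ms` treated as ectopic and
#' the later beat dropped).  The default denominator follows the literal
#' definition used by the processing protocol -- the total number of R-R
#' intervals, `n` -- while `denominator = "standard"` selects the usual HRV
#' convention of `n - 1` successive pairs.  Under the literal convention the
#' value lies in `[0, (n-1)/n]`; under the standard one in `[0, 1]`.
#'
#' @param rris Numeric vector of R-R intervals in ms, in temporal order.
#' @param config An [hrv_config()].
#'
#' @return A fraction, or `NA` when fewer than two gated intervals remain.
#' @export
#' @examples
#' pnn50(c(800, 900, 810, 805)) # 2 of 3 diffs exceed 50 ms; literal: 2/4
#' pnn50(c(800, 900, 810, 805), hrv_config(denominator = "standard"))
pnn50 <- function(rris, config = hrv_config()) {
  r <- rris[!is.na(rris) & rris >= config$rri_gate_ms[1] &
              rris <= config$rri_gate_ms[2]]
  if (length(r) >= 2) {
    ect <- which(abs(diff(r)) > config$max_successive_diff_ms)
    if (length(ect)) r <- r[-(ect + 1)]
  }
  n <- length(r)
  if (n < 2) {
    return(NA_real_)
  }
  exceed <- sum(abs(diff(r)) > config$threshold_ms)
  denom <- if (config$denominator == "literal") n else n - 1
  exceed / denom
}

#' Pre-sleep HRV summary for one night
#'
#' Partitions the window `[in_bed - window_minutes, in_bed)` into half-open
#' segments of `segment_minutes` (fifteen 2-minute segments by default),
#' computes pNN50 per segment with at least `min_rri_per_segment` gated
#' intervals, and summarises the night as the mean over valid segments.  The
#' summary is missing when fewer than `min_valid_segments` segments are
#' valid.
#'
#' @param stream Tibble with `timestamp` (POSIXct) and `rri_ms`.
#' @param in_bed POSIXct in-bed anchor.
#' @param config An [hrv_config()].
#'
#' @return One-row tibble: `n_valid_segments`, `pnn50_presleep`, and
#'   list-column `segment_pnn50`.
#' @export
presleep_hrv <- function(stream, in_bed, config = hrv_config()) {
  n_seg <- as.integer(config$window_minutes / config$segment_minutes)
  w0 <- in_bed - config$window_minutes * 60
  seg_of <- floor(as.numeric(stream$timestamp - w0, units = "secs") /
                    (config$segment_minutes * 60))
  keep <- seg_of >= 0 & seg_of < n_seg
  seg_vals <- purrr::map_dbl(seq_len(n_seg) - 1L, function(s) {
    r <- stream$rri_ms[keep & seg_of == s]
    if (length(r) < config$min_rri_per_segment) {
      return(NA_real_)
    }
    pnn50(r, config)
  })
  n_valid <- sum(!is.na(seg_vals))
  tibble(
    n_valid_segments = n_valid,
    pnn50_presleep = if (n_valid >= config$min_valid_segments) {
      mean(seg_vals, na.rm = TRUE)
    } else {
      NA_real_
    },
    segment_pnn50 = list(seg_vals)
  )
}

#' Nightly pre-sleep pNN50 for a cohort
#'
#' Joins each night's R-R stream to its diary in-bed anchor and summarises
#' the 30 minutes before bed via [presleep_hrv()].
#'
#' @param rri Tibble with `participant_id, date, timestamp, rri_ms`.
#' @param diary Diary tibble with `participant_id, date, in_bed`.
#' @param config An [hrv_config()].
#'
#' @return Tibble: `participant_id, date, n_valid_segments, pnn50_presleep`.
#' @export
hrv_nightly <- function(rri, diary, config = hrv_config()) {
  streams <- rri %>%
    dplyr::inner_join(diary %>% select(all_of(c("participant_id", "date",
                                                "in_bed"))),
                      by = c("participant_id", "date"))
  streams %>%
    group_by(.data$participant_id, .data$date) %>%
    dplyr::group_modify(function(df, key) {
      presleep_hrv(df, df$in_bed[1], config) %>%
        select(all_of(c("n_valid_segments", "pnn50_presleep")))
    }) %>%
    ungroup()
}
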