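#' Missingness configuration for the synthetic cohort
#'
#' Controls the two device-artefact processes the generator can inject into a
#' complete recording: battery gaps (both activity and lux samples removed)
#' and light-sensor occlusions, e.g. by a long sleeve (lux forced to zero,
#' activity kept).
#'
#' @param p_battery_gap_per_day Probability that a given participant-day
#'   contains one battery gap.
#' @param battery_gap_minutes Length-2 numeric, lower/upper bound (minutes) of
#'   the uniformly drawn battery-gap duration.
#' @param p_sleeve_occlusion_per_day Probability of one daytime lux occlusion
#'   per participant-day.
#' @param occlusion_minutes Length-2 numeric bounds (minutes) of the occlusion
#'   duration.
#'
#' @return A list of class `missingness_config`.
#' @export
#' @examples
#' missingness_config(p_battery_gap_per_day = 0.1)
missingness_config <- function(p_battery_gap_per_day = 0,
                               battery_gap_minutes = c(35, 120),
                               p_sleeve_occlusion_per_day = 0,
                               occlusion_minutes = c(1, 10)) {
  sc_assert(is.numeric(p_battery_gap_per_day) &&
              p_battery_gap_per_day >= 0 && p_battery_gap_per_day <= 1,
            "`p_battery_gap_per_day` must be a probability in [0, 1]",
            field = "p_battery_gap_per_day")
  sc_assert(is.numeric(p_sleeve_occlusion_per_day) &&
              p_sleeve_occlusion_per_day >= 0 && p_sleeve_occlusion_per_day <= 1,
            "`p_sleeve_occlusion_per_day` must be a probability in [0, 1]",
            field = "p_sleeve_occlusion_per_day")
  for (nm in c("battery_gap_minutes", "occlusion_minutes")) {
    v <- get(nm)
    sc_assert(is.numeric(v) && length(v) == 2 && all(v > 0) && v[1] <= v[2],
              paste0("`", nm, "` must be two positive increasing bounds"),
              field = nm)
  }
  structure(
    list(p_battery_gap_per_day = p_battery_gap_per_day,
         battery_gap_minutes = battery_gap_minutes,
         p_sleeve_occlusion_per_day = p_sleeve_occlusion_per_day,
         occlusion_minutes = occlusion_minutes),
    class = "missingness_config"
  )
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: a 14-day wrist-worn
#' recording per participant at 10-second sampling, a nightly pre-sleep R-R
#' stream, and a daily sleep diary.  Nightly true sleep efficiency follows a
#' logit-linear structural model
#' \deqn{\mathrm{logit}(SE_{id}) = \beta_0 + \beta_a z_{id} +
#'   \beta_e \tilde{A}^{ev}_{id} + \beta_l \tilde{L}^{18+}_{id} +
#'   \beta_p \mathrm{logit}(SE_{i,d-1}) + \varepsilon_{id}}
#' where \eqn{z} is a latent nightly arousal state (which also lowers
#' pre-sleep pNN50), \eqn{\tilde{A}^{ev}} the standardized evening
#' vector-magnitude mean, \eqn{\tilde{L}^{18+}} the standardized post-18:00
#' illuminance, and \eqn{\varepsilon \sim N(0, \sigma^2)}.  \eqn{\beta_0} is
#' calibrated at generation time so the marginal good-sleep rate
#' \eqn{P(SE \ge 0.90)} matches `prevalence_target`.
#'
#' @param n_participants Number of participants.
#' @param n_days Days of recording per participant (default 14, giving 13
#'   day-and-night data units).
#' @param seed Integer seed; together with the config it fully determines the
#'   cohort.
#' @param prevalence_target Target marginal good-sleep rate in (0, 1).
#' @param beta_arousal Coefficient (<= 0) of the latent arousal state on both
#'   the sleep-efficiency and the pNN50 path.
#' @param beta_evening_activity Coefficient (<= 0) of standardized evening
#'   activity.
#' @param beta_late_light Coefficient (<= 0) of standardized post-18:00 lux.
#' @param beta_prev_night Night-to-night carry-over coefficient in [0, 1) on
#'   the previous night's logit sleep efficiency.
#' @param noise_sd Standard deviation (>= 0) of the structural noise on the
#'   logit scale.
#' @param missingness A [missingness_config()].
#' @param pnn50_base Marginal pre-sleep pNN50 level (fraction) at arousal 0.
#' @param diary_noise_sd_min SD (minutes) of diary-reported time noise.
#' @param diary_arousal_shift_min Minutes per SD of arousal by which the
#'   reported bed and rise times are shifted (a generative coupling; zero it
#'   together with the betas for a fully decoupled null cohort).
#' @param beta0 Optional fixed intercept on the logit scale.  The default
#'   `NULL` calibrates the intercept at generation time so the marginal
#'   good-sleep rate matches `prevalence_target`; supplying a value skips
#'   calibration (useful for fully deterministic degenerate cohorts).
#'
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cohort_config(n_participants = 4, seed = 1)
cohort_config <- function(n_participants,
                          n_days = 14,
                          seed = 1L,
                          prevalence_target = 0.5,
                          beta_arousal = -0.8,
                          beta_evening_activity = -0.3,
                          beta_late_light = -0.3,
                          beta_prev_night = 0.35,
                          noise_sd = 0.6,
                          missingness = missingness_config(),
                          pnn50_base = 0.3,
                          diary_noise_sd_min = 10,
                          diary_arousal_shift_min = 2,
                          beta0 = NULL) {
  sc_assert(is.numeric(n_participants) && n_participants >= 1,
            "`n_participants` must be a positive count", field = "n_participants")
  sc_assert(is.numeric(n_days) && n_days >= 2,
            "`n_days` must be at least 2", field = "n_days")
  sc_assert(is.numeric(prevalence_target) &&
              prevalence_target > 0 && prevalence_target < 1,
            "`prevalence_target` must lie in (0, 1)", field = "prevalence_target")
  sc_assert(is.numeric(beta_arousal) && beta_arousal <= 0,
            "`beta_arousal` must be <= 0", field = "beta_arousal")
  sc_assert(is.numeric(beta_evening_activity) && beta_evening_activity <= 0,
            "`beta_evening_activity` must be <= 0", field = "beta_evening_activity")
  sc_assert(is.numeric(beta_late_light) && beta_late_light <= 0,
            "`beta_late_light` must be <= 0", field = "beta_late_light")
  sc_assert(is.numeric(beta_prev_night) &&
              beta_prev_night >= 0 && beta_prev_night < 1,
            "`beta_prev_night` must lie in [0, 1)", field = "beta_prev_night")
  sc_assert(is.numeric(noise_sd) && noise_sd >= 0,
            "`noise_sd` must be >= 0", field = "noise_sd")
  sc_assert(inherits(missingness, "missingness_config"),
            "`missingness` must be a missingness_config()", field = "missingness")
  sc_assert(is.numeric(pnn50_base) && pnn50_base >= 0 && pnn50_base < 1,
            "`pnn50_base` must lie in [0, 1)", field = "pnn50_base")
  structure(
    list(n_participants = as.integer(n_participants),
         n_days = as.integer(n_days),
         sample_interval = 10L,
         seed = as.integer(seed),
         prevalence_target = prevalence_target,
         beta_arousal = beta_arousal,
         beta_evening_activity = beta_evening_activity,
         beta_late_light = beta_late_light,
         beta_prev_night = beta_prev_night,
         noise_sd = noise_sd,
         missingness = missingness,
         pnn50_base = pnn50_base,
         diary_noise_sd_min = diary_noise_sd_min,
         diary_arousal_shift_min = diary_arousal_shift_min,
         beta0 = beta0),
    class = "cohort_config"
  )
}

#' Cole-Kripke scoring parameters
#'
#' The scorer computes, for each 60-second epoch \eqn{t},
#' \deqn{D_t = P \sum_{i=-4}^{+2} w_i \, a_{t+i} / c}
#' over the y-axis activity counts \eqn{a} and scores the epoch sleep when
#' \eqn{D_t < } `sleep_threshold`.  The source study does not print its
#' coefficients; the defaults shipped here are the one-minute-epoch weights of
#' the original 1992 validation study (scale 0.001; weights 106, 54, 58, 76,
#' 230, 74, 67; threshold 1), with epoch counts divided by 100 as in the
#' standard actigraphy-software implementation.  Every scored output records
#' `param_id` so results are traceable to a parameter set.
#'
#' @param scale Multiplicative scale \eqn{P}.
#' @param weights Seven nonnegative weights for epoch offsets -4..+2.
#' @param count_divisor Epoch counts are divided by this before weighting.
#' @param sleep_threshold Scores strictly below this are sleep.
#' @param onset_run_length Consecutive sleep epochs required to call sleep
#'   onset.
#' @param offset_run_length Consecutive sleep epochs required for the final
#'   awakening rule.
#' @param max_invalid_fraction Nights whose invalid-epoch fraction within the
#'   in-bed span exceeds this are dropped as unscorable.
#' @param param_id Identity tag recorded on every scored night.
#'
#' @return A list of class `ck_params`.
#' @export
#' @examples
#' ck_params()
ck_params <- function(scale = 0.001,
                      weights = c(106, 54, 58, 76, 230, 74, 67),
                      count_divisor = 100,
                      sleep_threshold = 1,
                      onset_run_length = 5L,
                      offset_run_length = 5L,
                      max_invalid_fraction = 0.1,
                      param_id = "cole1992-60s/v1") {
  sc_assert(is.numeric(scale) && scale > 0, "`scale` must be > 0",
            field = "scale")
  sc_assert(is.numeric(weights) && length(weights) == 7 && all(weights >= 0),
            "`weights` must be 7 nonnegative reals (offsets -4..+2)",
            field = "weights")
  sc_assert(is.numeric(count_divisor) && count_divisor > 0,
            "`count_divisor` must be > 0", field = "count_divisor")
  sc_assert(is.finite(sleep_threshold), "`sleep_threshold` must be finite",
            field = "sleep_threshold")
  sc_assert(onset_run_length >= 1 && offset_run_length >= 1,
            "run lengths must be >= 1", field = "onset_run_length")
  structure(
    list(scale = scale, weights = as.numeric(weights),
         count_divisor = count_divisor, sleep_threshold = sleep_threshold,
         onset_run_length = as.integer(onset_run_length),
         offset_run_length = as.integer(offset_run_length),
         max_invalid_fraction = max_invalid_fraction,
         param_id = param_id),
    class = "ck_params"
  )
}

#' HRV (pNN50) settings
#'
#' @param denominator `"literal"` divides the count of successive differences
#'   exceeding 50 ms by the total number of R-R intervals (n); `"standard"`
#'   divides by the number of successive pairs (n - 1).  Both conventions are
#'   implemented because the study text defines the former while the HRV
#'   literature uses the latter.
#' @param threshold_ms Successive-difference threshold, strictly exceeded.
#' @param rri_gate_ms Physiological gate: R-R intervals outside these bounds
#'   are dropped before analysis.
#' @param max_successive_diff_ms Successive differences larger than this are
#'   treated as ectopic artefacts and the later beat dropped.
#' @param segment_minutes Segment length inside the pre-sleep window.
#' @param window_minutes Length of the pre-sleep window before in-bed time.
#' @param min_valid_segments Minimum valid segments for a nightly summary.
#' @param min_rri_per_segment Minimum gated intervals per valid segment.
#'
#' @return A list of class `hrv_config`.
#' @export
hrv_config <- function(denominator = c("literal", "standard"),
                       threshold_ms = 50,
                       rri_gate_ms = c(300, 2000),
                       max_successive_diff_ms = 300,
                       segment_minutes = 2,
                       window_minutes = 30,
                       min_valid_segments = 5L,
                       min_rri_per_segment = 2L) {
  denominator <- match.arg(denominator)
  sc_assert(threshold_ms > 0, "`threshold_ms` must be > 0", field = "threshold_ms")
  sc_assert(length(rri_gate_ms) == 2 && rri_gate_ms[1] < rri_gate_ms[2],
            "`rri_gate_ms` must be increasing bounds", field = "rri_gate_ms")
  structure(
    list(denominator = denominator, threshold_ms = threshold_ms,
         rri_gate_ms = rri_gate_ms,
         max_successive_diff_ms = max_successive_diff_ms,
         segment_minutes = segment_minutes, window_minutes = window_minutes,
         min_valid_segments = as.integer(min_valid_segments),
         min_rri_per_segment = as.integer(min_rri_per_segment)),
    class = "hrv_config"
  )
}

#' Preprocessing thresholds
#'
#' @param activity_gap_min Runs of absent activity samples at least this long
#'   (minutes) exclude the day unit.  Comparison is inclusive (a run of
#'   exactly 30 minutes excludes).
#' @param lux_gap_min Runs of zero-or-absent lux at least this long (minutes)
#'   during the wake span exclude the day unit.
#' @param epoch_seconds Epoch length for aggregation.
#' @param activity_stat `"sum"` (counts per epoch, the actigraphy convention)
#'   or `"mean"`.
#'
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(activity_gap_min = 30,
                              lux_gap_min = 3,
                              epoch_seconds = 60L,
                              activity_stat = c("sum", "mean")) {
  activity_stat <- match.arg(activity_stat)
  sc_assert(activity_gap_min > 0 && lux_gap_min > 0,
            "gap thresholds must be positive", field = "activity_gap_min")
  structure(
    list(activity_gap_min = activity_gap_min, lux_gap_min = lux_gap_min,
         epoch_seconds = as.integer(epoch_seconds),
         activity_stat = activity_stat),
    class = "preprocess_config"
  )
}

#' Benchmark configuration
#'
#' @param methods Subset of `"gradient_boosting"`, `"convolutional_net"`,
#'   `"recurrent_net"`, `"logistic_regression"`.
#' @param sources Subset of `"device"`, `"diary"`, `"combined"`.
#' @param lengths Subset of 1, 2, 3 (days per prediction unit).
#' @param hrv_included Include the nightly pre-sleep pNN50 scalar.
#' @param n_folds Participant-grouped cross-validation folds.
#' @param stratified Stratify fold assignment by participant-level good-sleep
#'   rate.
#' @param seed Seed for fold assignment and the stochastic learners.
#' @param decision_threshold Probability threshold for accuracy; ties classify
#'   positive.
#' @param min_class_units Minimum units per class for a cell to be evaluable.
#' @param hyper Named list of per-method hyperparameters overriding the
#'   documented defaults (see [bench_default_hyper()]).
#'
#' @return A list of class `bench_config`.
#' @export
bench_config <- function(methods = c("gradient_boosting", "convolutional_net",
                                     "recurrent_net", "logistic_regression"),
                         sources = c("device", "diary", "combined"),
                         lengths = c(1L, 2L, 3L),
                         hrv_included = TRUE,
                         n_folds = 5L,
                         stratified = TRUE,
                         seed = 1L,
                         decision_threshold = 0.5,
                         min_class_units = 10L,
                         hyper = list()) {
  methods <- match.arg(methods, several.ok = TRUE)
  sources <- match.arg(sources, several.ok = TRUE)
  sc_assert(all(lengths %in% 1:3), "`lengths` must be a subset of {1, 2, 3}",
            field = "lengths", class = "sleepcast_domain_error")
  sc_assert(n_folds >= 2, "`n_folds` must be >= 2", field = "n_folds")
  sc_assert(decision_threshold > 0 && decision_threshold < 1,
            "`decision_threshold` must lie in (0, 1)",
            field = "decision_threshold")
  structure(
    list(methods = methods, sources = sources, lengths = as.integer(lengths),
         hrv_included = hrv_included, n_folds = as.integer(n_folds),
         stratified = stratified, seed = as.integer(seed),
         decision_threshold = decision_threshold,
         min_class_units = as.integer(min_class_units),
         hyper = modifyList(bench_default_hyper(), hyper)),
    class = "bench_config"
  )
}

#' Default benchmark hyperparameters
#'
#' Fixed, documented defaults; the bench compares model families, it does not
#' tune.
#'
#' @return Named list with one element per method.
#' @export
bench_default_hyper <- function() {
  list(
    gradient_boosting = list(nrounds = 150, eta = 0.1, max_depth = 3,
                             subsample = 0.8, colsample_bytree = 0.8,
                             min_child_weight = 2),
    logistic_regression = list(),
    convolutional_net = list(filters = 8, kernel = 5, stride = 2,
                             hidden = 16, epochs = 20, batch = 64,
                             lr = 0.01, l2 = 1e-4),
    recurrent_net = list(hidden = 8, dense = 16, epochs = 15, batch = 64,
                         lr = 0.01, l2 = 1e-4)
  )
}
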