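#' Pipeline configuration
#'
#' Bundles the per-stage configurations, the output directory and the log
#' level.  The single `seed` inside `cohort` fans out to stage-specific
#' derived seeds, so stages are rerunnable in isolation with stable
#' randomness.  A pipeline config round-trips losslessly through its YAML
#' file form ([write_pipeline_config()], [read_pipeline_config()]).
#'
#' @param cohort A [cohort_config()].
#' @param preprocess A [preprocess_config()].
#' @param ck A [ck_params()].
#' @param hrv An [hrv_config()].
#' @param features A [feature_spec()].
#' @param bench A [bench_config()].
#' @param out_dir Output directory for pipeline artifacts.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort,
                            preprocess = preprocess_config(),
                            ck = ck_params(),
                            hrv = hrv_config(),
                            features = feature_spec(),
                            bench = bench_config(),
                            out_dir = "sleepcast-out",
                            log_level = c("info", "quiet", "debug")) {
  log_level <- match.arg(log_level)
  sc_assert(inherits(cohort, "cohort_config"),
            "`cohort` must be a cohort_config()", field = "cohort")
  structure(
    list(cohort = cohort, preprocess = preprocess, ck = ck, hrv = hrv,
         features = features, bench = bench, out_dir = out_dir,
         log_level = log_level),
    class = "pipeline_config"
  )
}

sc_log <- function(pc, msg, level = "info") {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[pc$log_level]] >= lv[[level]]) {
    message(sprintf("[sleepcast %s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  }
}

# ---- YAML round trip -------------------------------------------------------

sc_strip <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), sc_strip)
  } else {
    x
  }
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(sc_strip(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  rebuild <- function(fields, ctor, drop = character()) {
    fields <- fields[setdiff(names(fields), drop)]
    do.call(ctor, fields)
  }
  co <- y$cohort
  co$missingness <- rebuild(co$missingness, missingness_config)
  co <- rebuild(co, cohort_config, drop = "sample_interval")
  be <- y$bench
  be$hyper <- be$hyper %||% list()
  pipeline_config(
    cohort = co,
    preprocess = rebuild(y$preprocess, preprocess_config),
    ck = rebuild(y$ck, ck_params),
    hrv = rebuild(y$hrv, hrv_config),
    features = rebuild(y$features, feature_spec),
    bench = rebuild(be, bench_config),
    out_dir = y$out_dir,
    log_level = y$log_level
  )
}

# ---- in-memory end-to-end study -------------------------------------------

#' Run the full analysis in memory, participant by participant
#'
#' Generates the cohort truth once (calibrating the good-sleep prevalence),
#' then streams each participant through recording synthesis, epoch
#' aggregation, exclusion detection, sleep scoring, HRV summarisation and
#' day-unit construction, discarding the raw streams as it goes.  This keeps
#' memory bounded for cohorts of hundreds of participants.
#'
#' @param config A [cohort_config()].
#' @param preprocess,ck,hrv,features Stage configurations.
#' @param progress Emit a message every 50 participants.
#' @param keep_epochs Retain the epoch series in the result (memory permitting).
#'
#' @return A list of class `sleepcast_study`: `day_units`, `nights`, `hrv`,
#'   `exclusions`, `diary`, `truth`, `accounting`, `config` (and `epochs`
#'   when `keep_epochs`).
#' @export
build_study <- function(config,
                        preprocess = preprocess_config(),
                        ck = ck_params(),
                        hrv = hrv_config(),
                        features = feature_spec(),
                        progress = FALSE,
                        keep_epochs = FALSE) {
  truth <- sc_cohort_truth(config)
  mc <- config$missingness
  inject <- mc$p_battery_gap_per_day > 0 || mc$p_sleeve_occlusion_per_day > 0

  parts <- purrr::map(seq_len(config$n_participants), function(i) {
    pid <- truth$profiles$participant_id[i]
    nights_i <- truth$nights[truth$nights$participant_id == pid, ]
    rec <- sc_participant_recording(truth$profiles[i, ], nights_i, config)
    gaps <- NULL
    if (inject) {
      inj <- inject_missingness(rec, mc,
                                seed = derive_seed(config$seed,
                                                   paste0("miss-", pid)))
      rec <- inj$recording
      gaps <- inj$gaps
    }
    diary_i <- sc_cohort_diary(nights_i)
    epochs_i <- aggregate_epochs(rec, preprocess)
    excl_i <- detect_exclusions(rec, diary_i, preprocess)
    rm(rec)
    nights_dev <- score_nights(epochs_i, diary_i, ck)
    rri_i <- sc_cohort_rri(list(nights = nights_i), config)
    hrv_i <- hrv_nightly(rri_i, diary_i, hrv)
    du_i <- build_day_units(epochs_i, diary_i, nights_dev, hrv_i, excl_i,
                            features)
    if (progress && i %% 50 == 0) {
      message("  ...", i, " participants processed")
    }
    list(du = du_i, nights = nights_dev, hrv = hrv_i, excl = excl_i,
         diary = diary_i, gaps = gaps,
         epochs = if (keep_epochs) epochs_i else NULL)
  })

  day_units <- bind_rows(purrr::map(parts, "du"))
  acct <- sc_unit_accounting(day_units)

  structure(
    list(
      day_units = day_units,
      nights = bind_rows(purrr::map(parts, "nights")),
      hrv = bind_rows(purrr::map(parts, "hrv")),
      exclusions = bind_rows(purrr::map(parts, "excl")),
      diary = bind_rows(purrr::map(parts, "diary")),
      gaps = bind_rows(purrr::map(parts, "gaps")),
      truth = truth$nights,
      accounting = acct,
      config = config,
      epochs = if (keep_epochs) bind_rows(purrr::map(parts, "epochs"))
    ),
    class = "sleepcast_study"
  )
}

#' Unit accounting in the flow-diagram shape
#'
#' Counts theoretical units, losses to each exclusion cause, unscorable
#' nights, and the units entering analysis; the rows are conserved:
#' theoretical = excluded + unscorable + analysis.
#'
#' @param day_units Day-unit tibble.
#' @return One-row tibble of counts.
#' @export
sc_unit_accounting <- function(day_units) {
  tibble(
    theoretical = nrow(day_units),
    excluded_activity_gap = sum(day_units$excluded &
                                  day_units$reason == "activity_gap_30min"),
    excluded_lux_gap = sum(day_units$excluded &
                             day_units$reason == "lux_gap_3min"),
    excluded_unresolvable = sum(day_units$excluded &
                                  day_units$reason == "unresolvable"),
    night_unscorable = sum(!day_units$excluded & !day_units$scorable),
    analysis = sum(day_units$valid),
    hrv_missing_among_valid = sum(day_units$valid &
                                    is.na(day_units$pnn50_presleep))
  )
}

#' @export
print.sleepcast_study <- function(x, ...) {
  cat("<sleepcast_study>\n")
  print(as.data.frame(x$accounting), row.names = FALSE)
  invisible(x)
}

# ---- file-based stages -----------------------------------------------------

sc_out_path <- function(pc, name) file.path(pc$out_dir, name)

sc_ensure_outdir <- function(pc) {
  ok <- dir.exists(pc$out_dir) ||
    suppressWarnings(dir.create(pc$out_dir, recursive = TRUE))
  probe <- file.path(pc$out_dir, ".write-probe")
  ok <- ok && isTRUE(tryCatch({
    writeLines("x", probe)
    unlink(probe)
    TRUE
  }, error = function(e) FALSE))
  if (!ok) {
    abort(paste0("output directory is not writable: ", pc$out_dir),
          class = "sleepcast_io_error", field = "out_dir")
  }
  invisible(TRUE)
}

sc_manifest_entry <- function(path, rows) {
  list(file = basename(path), rows = rows,
       bytes = as.numeric(file.size(path)))
}

sc_write_manifest <- function(pc, files, timings, extra = list()) {
  manifest <- c(list(
    config_hash = rlang::hash(sc_strip(pc)),
    seed = pc$cohort$seed,
    version = as.character(utils::packageVersion("sleepcast")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stage_timings_sec = timings,
    files = files
  ), extra)
  jsonlite::write_json(manifest, sc_out_path(pc, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort to disk
#'
#' Writes the recordings, R-R streams, diaries and latent truth as CSV files
#' under the configured output directory, together with a run manifest
#' listing every file with its row count.  Fails before writing anything if
#' the output directory is not writable.
#'
#' @param pc A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
pipeline_simulate <- function(pc) {
  sc_ensure_outdir(pc)
  t0 <- Sys.time()
  sc_log(pc, "simulating cohort")
  coh <- generate_cohort(pc$cohort)
  files <- list()
  p <- sc_out_path(pc, "recordings.csv")
  write_raw_recording(coh$recordings, p)
  files$recordings <- sc_manifest_entry(p, nrow(coh$recordings))
  p <- sc_out_path(pc, "rri.csv")
  write_rri(coh$rri, p)
  files$rri <- sc_manifest_entry(p, nrow(coh$rri))
  p <- sc_out_path(pc, "diary.csv")
  write_diary(coh$diary, p)
  files$diary <- sc_manifest_entry(p, nrow(coh$diary))
  p <- sc_out_path(pc, "latent_truth.csv")
  write_latent_truth(coh$truth, p)
  files$latent_truth <- sc_manifest_entry(p, nrow(coh$truth))
  timings <- list(simulate = round(as.numeric(Sys.time() - t0,
                                              units = "secs"), 2))
  gap_inventory <- if (nrow(coh$gaps)) {
    coh$gaps %>%
      mutate(start = sc_fmt_time(.data$start), end = sc_fmt_time(.data$end))
  } else {
    NULL
  }
  invisible(sc_write_manifest(pc, files, timings,
                              extra = list(injected_gaps = gap_inventory)))
}

#' Preprocess simulated files: epochs and exclusion report
#'
#' @param pc A [pipeline_config()].
#' @return Paths written, invisibly.
#' @export
pipeline_preprocess <- function(pc) {
  sc_ensure_outdir(pc)
  rec <- read_raw_recording(sc_out_path(pc, "recordings.csv"))
  diary <- read_diary(sc_out_path(pc, "diary.csv"))
  sc_log(pc, "aggregating epochs and applying exclusion rules")
  epochs <- aggregate_epochs(rec, pc$preprocess)
  excl <- detect_exclusions(rec, diary, pc$preprocess)
  write_epochs(epochs, sc_out_path(pc, "epochs.csv"))
  write_exclusions(excl, sc_out_path(pc, "exclusions.csv"))
  invisible(c(sc_out_path(pc, "epochs.csv"), sc_out_path(pc, "exclusions.csv")))
}

#' Score sleep from preprocessed epochs
#'
#' @param pc A [pipeline_config()].
#' @return Path written, invisibly.
#' @export
pipeline_score_sleep <- function(pc) {
  epochs <- read_epochs(sc_out_path(pc, "epochs.csv"))
  diary <- read_diary(sc_out_path(pc, "diary.csv"))
  sc_log(pc, "scoring nights")
  nights <- score_nights(epochs, diary, pc$ck)
  write_sleep_nights(nights, sc_out_path(pc, "nights_device.csv"))
  invisible(sc_out_path(pc, "nights_device.csv"))
}

#' Nightly pre-sleep HRV summaries
#'
#' @param pc A [pipeline_config()].
#' @return Path written, invisibly.
#' @export
pipeline_hrv <- function(pc) {
  rri <- read_rri(sc_out_path(pc, "rri.csv"))
  diary <- read_diary(sc_out_path(pc, "diary.csv"))
  sc_log(pc, "summarising pre-sleep HRV")
  hrv <- hrv_nightly(rri, diary, pc$hrv)
  readr::write_csv(hrv, sc_out_path(pc, "hrv_nightly.csv"), na = "")
  invisible(sc_out_path(pc, "hrv_nightly.csv"))
}

#' Assemble and write feature-unit tables
#'
#' Writes one CSV (+ JSON schema sidecar) per configured source x length
#' cell.
#'
#' @param pc A [pipeline_config()].
#' @return Paths written, invisibly.
#' @export
pipeline_featurize <- function(pc) {
  du <- sc_rebuild_day_units(pc)
  sc_log(pc, "assembling feature units")
  paths <- character()
  for (src in pc$bench$sources) {
    for (k in pc$bench$lengths) {
      units <- assemble_units(du, k = k, source = src,
                              hrv_included = pc$bench$hrv_included)
      p <- sc_out_path(pc, sprintf("feature_units_%s_%dd.csv", src, k))
      write_feature_units(units, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

# rebuild the day-unit table (including sequence grids) from staged files
sc_rebuild_day_units <- function(pc) {
  epochs <- read_epochs(sc_out_path(pc, "epochs.csv"))
  diary <- read_diary(sc_out_path(pc, "diary.csv"))
  nights <- read_sleep_nights(sc_out_path(pc, "nights_device.csv"))
  hrv <- readr::read_csv(sc_out_path(pc, "hrv_nightly.csv"),
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           date = readr::col_date(),
                           n_valid_segments = readr::col_integer(),
                           pnn50_presleep = readr::col_double()
                         ), na = "", progress = FALSE)
  rec <- read_raw_recording(sc_out_path(pc, "recordings.csv"))
  excl <- detect_exclusions(rec, diary, pc$preprocess)
  build_day_units(epochs, diary, nights, hrv, excl, pc$features)
}

#' Run the benchmark from staged files
#'
#' @param pc A [pipeline_config()].
#' @return The `bench_report`, invisibly.
#' @export
pipeline_bench <- function(pc) {
  du <- sc_rebuild_day_units(pc)
  sc_log(pc, "running model bench")
  rep <- run_bench(du, pc$bench)
  write_bench_report(rep, sc_out_path(pc, "bench_report.csv"))
  invisible(rep)
}

#' Run the full pipeline end to end
#'
#' Executes simulate, preprocess, score, HRV, featurize and bench in memory
#' (via [build_study()]), persists the intermediate tables, the
#' unit-accounting table and the benchmark report, and writes a manifest
#' with per-stage timings and row counts.  Any stage failure aborts with the
#' stage name.
#'
#' @param pc A [pipeline_config()].
#' @return List with the `bench_report`, the accounting table and the
#'   manifest.
#' @export
pipeline_run_all <- function(pc) {
  sc_ensure_outdir(pc)
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t0) round(as.numeric(Sys.time() - t0, units = "secs"), 2)

  t0 <- tic()
  sc_log(pc, "building study (simulate + preprocess + score + hrv + features)")
  study <- tryCatch(
    build_study(pc$cohort, pc$preprocess, pc$ck, pc$hrv, pc$features),
    error = function(e) {
      abort(paste0("stage build_study failed: ", conditionMessage(e)),
            class = "sleepcast_stage_error")
    }
  )
  timings$build_study <- toc(t0)

  files <- list()
  wr <- function(x, name, writer = readr::write_csv) {
    p <- sc_out_path(pc, name)
    if (identical(writer, readr::write_csv)) {
      readr::write_csv(x, p, na = "")
    } else {
      writer(x, p)
    }
    files[[name]] <<- sc_manifest_entry(p, nrow(x))
  }
  wr(study$diary, "diary.csv", write_diary)
  wr(study$truth %>%
       select(all_of(c("participant_id", "date", "in_study", "arousal_z",
                       "true_sleep_efficiency", "true_good_sleep",
                       "true_in_bed", "true_out_of_bed", "target_pnn50"))),
     "latent_truth.csv", write_latent_truth)
  wr(study$nights, "nights_device.csv", write_sleep_nights)
  wr(study$hrv, "hrv_nightly.csv")
  wr(study$exclusions, "exclusions.csv", write_exclusions)
  wr(study$accounting, "unit_accounting.csv")

  t0 <- tic()
  sc_log(pc, "running model bench")
  report <- tryCatch(
    run_bench(study$day_units, pc$bench),
    error = function(e) {
      abort(paste0("stage bench failed: ", conditionMessage(e)),
            class = "sleepcast_stage_error")
    }
  )
  timings$bench <- toc(t0)
  p <- sc_out_path(pc, "bench_report.csv")
  write_bench_report(report, p)
  files[["bench_report.csv"]] <- sc_manifest_entry(p, nrow(report))

  manifest <- sc_write_manifest(pc, files, timings,
                                extra = list(
                                  accounting = as.list(study$accounting)
                                ))
  sc_log(pc, "done")
  list(report = report, accounting = study$accounting, manifest = manifest)
}

#' Read staged epoch or night CSVs
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_epochs <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    epoch_start = sc_time_col(),
    y_count = readr::col_double(), vm_count = readr::col_double(),
    mean_lux = readr::col_double(), n_samples = readr::col_integer(),
    valid = readr::col_logical()
  ), na = "", progress = FALSE) %>%
    mutate(epoch_start = sc_time(as.numeric(.data$epoch_start)))
}

#' @rdname read_epochs
#' @export
read_sleep_nights <- function(path) {
  out <- readr::read_csv(path, na = "", progress = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           date = readr::col_date(),
                           in_bed = sc_time_col(),
                           sleep_onset = sc_time_col(),
                           wake_time = sc_time_col(),
                           out_of_bed = sc_time_col(),
                           .default = readr::col_guess()
                         ))
  out %>%
    mutate(across(all_of(c("in_bed", "sleep_onset", "wake_time",
                           "out_of_bed")),
                  ~ sc_time(as.numeric(.x))))
}
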