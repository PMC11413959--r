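# Plain-text interchange formats.  All timestamps are written as ISO-8601
# timezone-naive local clock times; intervals are half-open.

sc_fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S")

sc_time_col <- function() {
  readr::col_datetime(format = "%Y-%m-%dT%H:%M:%S")
}

#' Read and write the raw-recording CSV dialect
#'
#' Header `participant_id,timestamp,axis_x,axis_y,axis_z,lux`; an absent lux
#' measurement is an empty field.
#'
#' @param recording Raw recording tibble.
#' @param path File path.
#' @return `read_raw_recording()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_raw_recording <- function(recording, path) {
  out <- recording %>% mutate(timestamp = sc_fmt_time(.data$timestamp))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_raw_recording
#' @export
read_raw_recording <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = sc_time_col(),
    axis_x = readr::col_integer(), axis_y = readr::col_integer(),
    axis_z = readr::col_integer(), lux = readr::col_double()
  ), na = "", progress = FALSE) %>%
    mutate(timestamp = sc_time(as.numeric(.data$timestamp)))
}

#' Read and write the sleep-diary CSV dialect
#'
#' Header `participant_id,date,in_bed,sleep_onset_latency_min,n_awakenings,
#' sleep_time,wake_time,out_of_bed,caffeine,alcohol,nap` (flags 0/1),
#' following the consensus diary items.
#'
#' @param diary Diary tibble.
#' @param path File path.
#' @return The tibble (reader) or `path`, invisibly (writer).
#' @export
write_diary <- function(diary, path) {
  out <- diary %>%
    mutate(across(all_of(c("in_bed", "sleep_time", "wake_time",
                           "out_of_bed")), sc_fmt_time))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_diary
#' @export
read_diary <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_date(),
    in_bed = sc_time_col(), sleep_time = sc_time_col(),
    wake_time = sc_time_col(), out_of_bed = sc_time_col(),
    sleep_onset_latency_min = readr::col_double(),
    n_awakenings = readr::col_integer(),
    caffeine = readr::col_integer(), alcohol = readr::col_integer(),
    nap = readr::col_integer()
  ), na = "", progress = FALSE) %>%
    mutate(across(all_of(c("in_bed", "sleep_time", "wake_time",
                           "out_of_bed")),
                  ~ sc_time(as.numeric(.x))))
}

#' Read and write the R-R interval stream CSV
#'
#' Header `participant_id,timestamp,rri_ms` (plus `date` tagging the night).
#'
#' @param rri R-R stream tibble.
#' @param path File path.
#' @return The tibble (reader) or `path`, invisibly (writer).
#' @export
write_rri <- function(rri, path) {
  out <- rri %>%
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%OS3"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_rri
#' @export
read_rri <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_date(),
    timestamp = readr::col_datetime(format = "%Y-%m-%dT%H:%M:%OS"),
    rri_ms = readr::col_double()
  ), na = "", progress = FALSE) %>%
    mutate(timestamp = sc_time(as.numeric(.data$timestamp)))
}

#' Write an epoch series, scored nights, latent truth or exclusion report
#'
#' Documented CSV headers; times ISO-8601; sleep efficiency as a decimal
#' fraction; list-columns (run inventories, per-segment values) serialised
#' as semicolon-joined lists.
#'
#' @param x Table to write.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  out <- x %>% mutate(epoch_start = sc_fmt_time(.data$epoch_start))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_epochs
#' @export
write_sleep_nights <- function(x, path) {
  out <- x %>%
    mutate(across(dplyr::where(~ inherits(.x, "POSIXct")), sc_fmt_time))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_epochs
#' @export
write_latent_truth <- function(x, path) {
  write_sleep_nights(x, path)
}

#' @rdname write_epochs
#' @export
write_exclusions <- function(x, path) {
  ser <- function(runs) {
    purrr::map_chr(runs, function(r) {
      if (!nrow(r)) return("")
      paste(sprintf("%s/%s", sc_fmt_time(sc_time(r$start)),
                    sc_fmt_time(sc_time(r$end))), collapse = ";")
    })
  }
  out <- x %>%
    mutate(activity_gap_runs = ser(.data$activity_gap_runs),
           lux_zero_runs = ser(.data$lux_zero_runs))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write assembled feature units with a JSON schema sidecar
#'
#' The CSV holds the scalar features with the label column last; the sidecar
#' (`<path>.schema.json`) records the feature names and order, the feature
#' spec version, the source and the unit length.
#'
#' @param units A `feature_units` tibble ([assemble_units()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_units <- function(units, path) {
  scalars <- as_tibble(units) %>% select(-all_of("seq"))
  scalars <- scalars[, c(setdiff(names(scalars), "label"), "label")]
  readr::write_csv(scalars %>% mutate(label = as.integer(.data$label)),
                   path, na = "")
  schema <- list(
    feature_names = setdiff(names(scalars),
                            c("participant_id", "date", "label")),
    spec_version = attr(units, "spec_version"),
    source = attr(units, "source"),
    k = attr(units, "k"),
    hrv_included = attr(units, "hrv_included"),
    label_column = "label"
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a benchmark report as CSV plus full-detail JSON
#'
#' @param report A `bench_report`.
#' @param path CSV path; fold-level detail goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_bench_report <- function(report, path) {
  flat <- as_tibble(report) %>% select(-all_of("folds"))
  readr::write_csv(flat, path, na = "")
  detail <- list(
    seed = attr(report, "seed"),
    config_hash = attr(report, "config_hash"),
    cells = purrr::pmap(as_tibble(report), function(...) {
      row <- list(...)
      row$folds <- as.data.frame(row$folds)
      row
    })
  )
  jsonlite::write_json(detail, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
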