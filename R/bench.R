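#' Classification accuracy at a probability threshold
#'
#' Exact confusion-matrix arithmetic: the fraction of predictions (true
#' positives plus true negatives) that match the labels.  Predicted
#' probabilities at or above `threshold` classify positive (ties positive).
#'
#' @param labels Logical or 0/1 vector.
#' @param predictions Predicted probabilities (or hard 0/1 values).
#' @param threshold Decision threshold.
#'
#' @return Fraction correct.
#' @export
#' @examples
#' evaluate_accuracy(c(1, 0, 1, 0), c(1, 0, 0, 0))
evaluate_accuracy <- function(labels, predictions, threshold = 0.5) {
  if (length(labels) != length(predictions) || length(labels) < 1) {
    abort("`labels` and `predictions` must have equal length >= 1",
          class = "sleepcast_validation_error", field = "predictions")
  }
  mean((predictions >= threshold) == as.logical(labels))
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney form over pooled predictions: the probability that a random
#' positive outranks a random negative, with midranks for ties.
#'
#' @param labels Logical or 0/1 vector with both classes present.
#' @param predictions Predicted probabilities.
#'
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
#' @examples
#' evaluate_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2))
evaluate_auc <- function(labels, predictions) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(predictions)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# participant-grouped fold assignment, optionally stratified by the
# participant-level good-sleep rate
sc_make_folds <- function(participant_id, label, n_folds, stratified, seed) {
  with_seed(seed, {
    rates <- tibble(participant_id = participant_id, label = label) %>%
      group_by(.data$participant_id) %>%
      summarise(rate = mean(.data$label), .groups = "drop")
    rates <- rates[sample.int(nrow(rates)), ]
    if (stratified) {
      rates <- rates %>% arrange(.data$rate)
    }
    rates$fold <- rep_len(seq_len(n_folds), nrow(rates))
    fold_of <- setNames(rates$fold, rates$participant_id)
    unname(fold_of[participant_id])
  })
}

#' Run the prediction benchmark over the method x source x length grid
#'
#' For every requested cell, assembles the k-day units from the day-unit
#' table, assigns participant-grouped (optionally stratified) folds, trains
#' the method on each training split, pools the out-of-fold predicted
#' probabilities, and reports accuracy at the decision threshold and AUC by
#' the rank statistic.  Cells with fewer than `min_class_units` units in
#' either class are reported as not evaluable and the run continues.
#' Gradient boosting and logistic regression are deterministic given the
#' seed; the neural methods are seeded-stochastic.
#'
#' @param day_units Day-unit tibble ([build_day_units()]).
#' @param config A [bench_config()].
#'
#' @return A tibble of class `bench_report`: one row per (method, source, k)
#'   with `n_units`, `prevalence`, `accuracy`, `auc`, `evaluable` and a
#'   `folds` list-column of fold-level metrics.  The config, seed and a
#'   config hash are attached as attributes.
#' @export
run_bench <- function(day_units, config = bench_config()) {
  grid <- tidyr::expand_grid(method = config$methods,
                             source = config$sources,
                             k = config$lengths)
  assembled <- list()
  for (src in config$sources) {
    for (k in config$lengths) {
      assembled[[paste(src, k)]] <-
        assemble_units(day_units, k = k, source = src,
                       hrv_included = config$hrv_included)
    }
  }

  rows <- purrr::pmap(grid, function(method, source, k) {
    units <- assembled[[paste(source, k)]]
    n1 <- sum(units$label)
    n0 <- sum(!units$label)
    base <- tibble(method = method, source = source, k = k,
                   n_units = nrow(units),
                   prevalence = if (nrow(units)) mean(units$label) else NA_real_,
                   accuracy = NA_real_, auc = NA_real_, evaluable = FALSE,
                   folds = list(tibble()))
    if (n1 < config$min_class_units || n0 < config$min_class_units) {
      return(base)
    }
    fold <- sc_make_folds(units$participant_id, units$label, config$n_folds,
                          config$stratified,
                          derive_seed(config$seed, "folds"))
    pred <- rep(NA_real_, nrow(units))
    fold_rows <- list()
    for (f in sort(unique(fold))) {
      te <- fold == f
      if (!any(te) || !any(!te)) next
      seed_f <- derive_seed(config$seed, paste(method, source, k, f))
      p <- sc_fit_predict(method, units[!te, ], units[te, ],
                          config$hyper, seed_f,
                          config$decision_threshold)
      pred[te] <- p
      fold_rows[[length(fold_rows) + 1]] <- tibble(
        fold = f, n = sum(te),
        accuracy = evaluate_accuracy(units$label[te], p,
                                     config$decision_threshold),
        auc = evaluate_auc(units$label[te], p)
      )
    }
    ok <- !is.na(pred)
    base$accuracy <- evaluate_accuracy(units$label[ok], pred[ok],
                                       config$decision_threshold)
    base$auc <- evaluate_auc(units$label[ok], pred[ok])
    base$evaluable <- TRUE
    base$folds <- list(bind_rows(fold_rows))
    base
  })

  out <- bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "seed") <- config$seed
  attr(out, "config_hash") <- rlang::hash(config)
  class(out) <- c("bench_report", class(tibble()))
  out
}

#' Compare data lengths within a benchmark report
#'
#' Returns per method-and-source deltas of accuracy and AUC between
#' consecutive data lengths, and the mean of each metric by length across
#' cells.
#'
#' @param report A `bench_report`.
#'
#' @return List with `deltas` (per method/source/length-pair) and
#'   `by_length` (mean accuracy/AUC per k).  Empty tibbles when fewer than
#'   two lengths are present.
#' @export
compare_lengths <- function(report) {
  rep_ok <- report %>% filter(.data$evaluable)
  if (length(unique(rep_ok$k)) < 2) {
    return(list(deltas = tibble(), by_length = tibble()))
  }
  deltas <- rep_ok %>%
    arrange(.data$method, .data$source, .data$k) %>%
    group_by(.data$method, .data$source) %>%
    mutate(d_accuracy = .data$accuracy - lag(.data$accuracy),
           d_auc = .data$auc - lag(.data$auc),
           from_k = lag(.data$k)) %>%
    ungroup() %>%
    filter(!is.na(.data$from_k)) %>%
    select(all_of(c("method", "source", "from_k", "k",
                    "d_accuracy", "d_auc")))
  by_length <- rep_ok %>%
    group_by(.data$k) %>%
    summarise(mean_accuracy = mean(.data$accuracy),
              mean_auc = mean(.data$auc),
              n_cells = dplyr::n(), .groups = "drop")
  list(deltas = deltas, by_length = by_length)
}

#' @export
print.bench_report <- function(x, ...) {
  cat("<bench_report>  seed:", attr(x, "seed"),
      " hash:", substr(attr(x, "config_hash"), 1, 8), "\n")
  NextMethod()
}

#' Render a benchmark report as an aligned accuracy/AUC table
#'
#' One row block per method with accuracy and AUC lines, columns by source
#' and data length, mirroring the familiar performance-table layout.
#'
#' @param report A `bench_report`.
#' @return Character vector of formatted lines (also printed).
#' @export
format_bench_table <- function(report) {
  cells <- report %>%
    mutate(col = paste0(.data$source, " ", .data$k, "d"))
  cols <- unique(cells$col)
  lines <- c(sprintf("%-22s %-9s %s", "Method", "Metric",
                     paste(sprintf("%10s", cols), collapse = "")))
  for (m in unique(cells$method)) {
    for (metric in c("accuracy", "auc")) {
      vals <- purrr::map_chr(cols, function(cl) {
        v <- cells[[metric]][cells$method == m & cells$col == cl]
        if (!length(v) || is.na(v[1])) "     --" else sprintf("%10.2f", v[1])
      })
      lines <- c(lines, sprintf("%-22s %-9s %s", m, metric,
                                paste(vals, collapse = "")))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
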