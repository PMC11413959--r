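#' Tidy a benchmark report
#'
#' One row per (method, source, length, metric) with the pooled value and
#' the across-fold mean and standard deviation.
#'
#' @param x A `bench_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bench_report <- function(x, ...) {
  as_tibble(x) %>%
    mutate(fold_detail = .data$folds) %>%
    tidyr::pivot_longer(cols = all_of(c("accuracy", "auc")),
                        names_to = "metric", values_to = "value") %>%
    mutate(
      fold_mean = purrr::map2_dbl(.data$fold_detail, .data$metric,
                                  ~ if (nrow(.x)) mean(.x[[.y]]) else NA_real_),
      fold_sd = purrr::map2_dbl(.data$fold_detail, .data$metric,
                                ~ if (nrow(.x)) sd(.x[[.y]]) else NA_real_)
    ) %>%
    select(all_of(c("method", "source", "k", "metric", "value",
                    "fold_mean", "fold_sd", "n_units", "evaluable")))
}

#' Summarise a benchmark report in one row
#'
#' @param x A `bench_report`.
#' @param ... Unused.
#' @return One-row tibble: cells evaluated, grand means, the best cell.
#' @export
glance.bench_report <- function(x, ...) {
  ok <- as_tibble(x) %>% filter(.data$evaluable)
  best <- ok %>% arrange(dplyr::desc(.data$auc)) %>% slice(1)
  tibble(
    n_cells = nrow(x),
    n_evaluable = nrow(ok),
    mean_accuracy = mean(ok$accuracy),
    mean_auc = mean(ok$auc),
    best_method = if (nrow(best)) best$method else NA_character_,
    best_source = if (nrow(best)) best$source else NA_character_,
    best_k = if (nrow(best)) best$k else NA_integer_,
    best_auc = if (nrow(best)) best$auc else NA_real_,
    seed = attr(x, "seed")
  )
}

#' Plot a benchmark report
#'
#' Accuracy and AUC per cell, by data length, faceted by source, coloured by
#' method.
#'
#' @param object A `bench_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bench_report <- function(object, ...) {
  dat <- tidy(object) %>% filter(.data$evaluable)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$k), y = .data$value,
                                    colour = .data$method,
                                    group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(metric ~ source) +
    ggplot2::labs(x = "data length (days)", y = NULL, colour = "method",
                  title = "Next-sleep prediction performance") +
    ggplot2::theme_minimal()
}

#' Actogram-style plot of an epoch series
#'
#' Activity (vector-magnitude counts per epoch) over clock time, one
#' horizontal band per day, with lux overlaid as colour.
#'
#' @param epochs Epoch tibble ([aggregate_epochs()]), one participant.
#' @return A ggplot object.
#' @export
plot_actogram <- function(epochs) {
  dat <- epochs %>%
    mutate(day = as.Date(.data$epoch_start),
           hour = as.numeric(.data$epoch_start -
                               sc_time(paste(as.Date(.data$epoch_start),
                                             "00:00:00")),
                             units = "hours"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hour, y = .data$vm_count)) +
    ggplot2::geom_col(ggplot2::aes(fill = log10(1 + .data$mean_lux)),
                      width = 1 / 60) +
    ggplot2::facet_grid(day ~ .) +
    ggplot2::scale_fill_viridis_c(name = "log10 lux") +
    ggplot2::labs(x = "clock hour", y = "VM counts / epoch") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}
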