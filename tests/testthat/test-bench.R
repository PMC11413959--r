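test_that("accuracy is exact confusion-matrix arithmetic", {
  expect_equal(evaluate_accuracy(c(1, 0, 1, 0), c(1, 0, 0, 0)), 0.75)
  expect_equal(evaluate_accuracy(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1)
  # ties at the threshold classify positive
  expect_equal(evaluate_accuracy(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(evaluate_accuracy(c(1, 0), c(1)),
               class = "sleepcast_validation_error")

  set.seed(10)
  y <- rbinom(1000, 1, 0.4)
  p <- runif(1000)
  correct <- 0
  for (i in 1:1000) {
    hard <- if (p[i] >= 0.5) 1 else 0
    if (hard == y[i]) correct <- correct + 1
  }
  expect_equal(evaluate_accuracy(y, p), correct / 1000)
})

test_that("AUC equals the Mann-Whitney rank statistic", {
  expect_equal(evaluate_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1)
  expect_equal(evaluate_auc(c(0, 1, 1, 0), c(0.9, 0.8, 0.3, 0.2)), 0.5)
  # uninformative constant classifier
  expect_equal(evaluate_auc(rep(c(1, 0), 10), rep(0.5, 20)), 0.5)
  expect_true(is.na(evaluate_auc(rep(1, 5), runif(5))))

  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- runif(60)
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                          direction = "<")))
    expect_equal(evaluate_auc(y, p), ref, tolerance = 1e-12)
  }
})

test_that("fold assignment is grouped by participant", {
  set.seed(12)
  pid <- rep(sprintf("P%02d", 1:17), each = 13)
  lab <- rbinom(length(pid), 1, 0.5) == 1
  fold <- sleepcast:::sc_make_folds(pid, lab, n_folds = 5,
                                    stratified = TRUE, seed = 1)
  per <- tapply(fold, pid, function(f) length(unique(f)))
  expect_true(all(per == 1))
  expect_equal(sort(unique(fold)), 1:5)
})

test_that("the bench is deterministic and cells below minimum are flagged", {
  st <- small_study()
  cfg <- bench_config(methods = c("gradient_boosting", "logistic_regression"),
                      sources = "combined", lengths = 1L,
                      hrv_included = FALSE, n_folds = 3, seed = 21)
  r1 <- run_bench(st$day_units, cfg)
  r2 <- run_bench(st$day_units, cfg)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_true(all(r1$evaluable))
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))

  # single-class day units: not evaluable, run continues
  du <- st$day_units
  du$night_good <- TRUE
  r3 <- run_bench(du, cfg)
  expect_true(all(!r3$evaluable))
  expect_true(all(is.na(r3$accuracy)))
})

test_that("no participant appears in both train and test of any fold", {
  st <- small_study()
  u <- assemble_units(st$day_units, 1, "combined", hrv_included = FALSE)
  fold <- sleepcast:::sc_make_folds(u$participant_id, u$label, 4, TRUE, 2)
  for (f in unique(fold)) {
    expect_equal(
      length(intersect(unique(u$participant_id[fold == f]),
                       unique(u$participant_id[fold != f]))), 0)
  }
})

test_that("length comparison reports per-cell deltas and means", {
  rep <- tibble::tibble(
    method = rep("gradient_boosting", 2),
    source = "combined", k = c(1L, 2L),
    n_units = c(100L, 90L), prevalence = 0.5,
    accuracy = c(0.70, 0.73), auc = c(0.69, 0.72),
    evaluable = TRUE, folds = list(tibble::tibble())
  )
  class(rep) <- c("bench_report", class(tibble::tibble()))
  cl <- compare_lengths(rep)
  expect_equal(cl$deltas$d_auc, 0.03)
  expect_equal(cl$deltas$d_accuracy, 0.03)
  expect_equal(cl$by_length$mean_auc, c(0.69, 0.72))

  # equal cells give zero deltas
  rep$auc <- c(0.7, 0.7)
  rep$accuracy <- c(0.7, 0.7)
  cl2 <- compare_lengths(rep)
  expect_equal(cl2$deltas$d_auc, 0)

  # single length: empty summary
  expect_equal(nrow(compare_lengths(rep[1, ])$deltas), 0)
})

test_that("tidy, glance and autoplot work on a bench report", {
  st <- small_study()
  cfg <- bench_config(methods = "logistic_regression",
                      sources = c("combined", "diary"), lengths = c(1L, 2L),
                      hrv_included = FALSE, n_folds = 3, seed = 5)
  rep <- run_bench(st$day_units, cfg)
  td <- generics::tidy(rep)
  expect_true(all(c("method", "source", "k", "metric", "value") %in% names(td)))
  expect_equal(nrow(td), 2 * nrow(rep))
  gl <- generics::glance(rep)
  expect_equal(nrow(gl), 1)
  expect_true(gl$n_evaluable <= gl$n_cells)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
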