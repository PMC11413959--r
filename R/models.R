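# Per-method fit/predict wrappers used by the benchmark harness.  Gradient
# boosting consumes the raw feature matrix with native missing-value
# handling; logistic regression and the neural heads receive training-fold
# mean imputation, standardisation, and an explicit missingness mask.

sc_feature_matrix <- function(units) {
  drop <- c("participant_id", "date", "seq", "label")
  cols <- setdiff(names(units), drop)
  m <- as.matrix(as_tibble(units)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# impute with training means, standardise by training moments, and append a
# missingness mask for columns that are ever missing in training data
sc_prep_scalars <- function(train, test) {
  mu <- colMeans(train, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  sdv <- apply(train, 2, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  has_na <- colSums(is.na(train)) > 0
  std <- function(m) {
    mask <- is.na(m)
    for (j in seq_len(ncol(m))) m[mask[, j], j] <- mu[j]
    m <- sweep(sweep(m, 2, mu, `-`), 2, sdv, `/`)
    if (any(has_na)) {
      mm <- mask[, has_na, drop = FALSE] * 1
      colnames(mm) <- paste0("miss_", colnames(m)[has_na])
      m <- cbind(m, mm)
    }
    m
  }
  list(train = std(train), test = std(test))
}

sc_fit_predict <- function(method, train_units, test_units, hyper, seed,
                           decision_threshold = 0.5) {
  xtr <- sc_feature_matrix(train_units)
  xte <- sc_feature_matrix(test_units)
  ytr <- as.numeric(train_units$label)

  if (method == "gradient_boosting") {
    hp <- hyper$gradient_boosting
    dtr <- xgboost::xgb.DMatrix(xtr, label = ytr, missing = NA)
    bst <- with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    max_depth = hp$max_depth, subsample = hp$subsample,
                    colsample_bytree = hp$colsample_bytree,
                    min_child_weight = hp$min_child_weight,
                    nthread = 1, seed = seed),
      data = dtr, nrounds = hp$nrounds, verbose = 0
    ))
    return(predict(bst, xgboost::xgb.DMatrix(xte, missing = NA)))
  }

  prep <- sc_prep_scalars(xtr, xte)

  if (method == "logistic_regression") {
    df_tr <- as.data.frame(prep$train)
    df_te <- as.data.frame(prep$test)
    names(df_te) <- names(df_tr) <- paste0("f", seq_len(ncol(df_tr)))
    df_tr$.y <- ytr
    fit <- suppressWarnings(glm(.y ~ ., data = df_tr, family = binomial()))
    return(suppressWarnings(
      unname(predict(fit, newdata = df_te, type = "response"))
    ))
  }

  if (method == "convolutional_net") {
    mod <- sc_cnn_fit(train_units$seq, prep$train, ytr,
                      hyper$convolutional_net, seed)
    return(sc_cnn_predict(mod, test_units$seq, prep$test))
  }

  if (method == "recurrent_net") {
    mod <- sc_lstm_fit(train_units$seq, prep$train, ytr,
                       hyper$recurrent_net, seed)
    return(sc_lstm_predict(mod, test_units$seq, prep$test))
  }

  abort(paste0("unknown method: ", method),
        class = "sleepcast_domain_error", field = "method")
}
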