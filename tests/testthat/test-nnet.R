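# The small neural learners ship their own analytic gradients; these tests
# verify them against numerical differentiation and check that both nets can
# actually learn a separable problem.

num_grad <- function(loss_fn, params, eps = 1e-5) {
  grads <- params
  for (k in names(params)) {
    g <- params[[k]]
    for (i in seq_along(g)) {
      p1 <- params
      p1[[k]][i] <- p1[[k]][i] + eps
      p2 <- params
      p2[[k]][i] <- p2[[k]][i] - eps
      g[i] <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
    }
    grads[[k]] <- g
  }
  grads
}

reg_loss <- function(par, p, y, l2) {
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  bce + l2 * (sum(par$W1^2) + sum(par$w2^2))
}

test_that("convolutional-net gradients match numerical differentiation", {
  set.seed(31)
  n <- 5
  seqs <- lapply(1:n, function(i) matrix(rnorm(12 * 2), 12, 2))
  scal <- matrix(rnorm(n * 3), n, 3)
  y <- c(1, 0, 1, 1, 0)
  hyper <- list(filters = 3, kernel = 4, stride = 2, hidden = 4, l2 = 1e-3)
  ic <- sleepcast:::sc_im2col(seqs, hyper$kernel, hyper$stride)
  par <- sleepcast:::with_seed(1, sleepcast:::sc_cnn_init(
    ncol(ic$patches), hyper$filters, 3, hyper$hidden))

  loss_fn <- function(pp) {
    fw <- sleepcast:::sc_cnn_forward(pp, ic$patches, ic$t_out, scal)
    reg_loss(pp, fw$p, y, hyper$l2) +
      hyper$l2 * (sum(pp$Wc^2))
  }
  fw <- sleepcast:::sc_cnn_forward(par, ic$patches, ic$t_out, scal)
  an <- sleepcast:::sc_cnn_backward(par, ic$patches, ic$t_out, scal, fw, y,
                                    hyper$l2)
  nu <- num_grad(loss_fn, par)
  for (k in names(par)) {
    expect_lt(max(abs(an[[k]] - nu[[k]])), 1e-5)
  }
})

test_that("LSTM gradients match numerical differentiation", {
  set.seed(32)
  n <- 4
  seqs <- lapply(1:n, function(i) matrix(rnorm(9 * 2), 9, 2))
  x <- sleepcast:::sc_seq_array(seqs)
  scal <- matrix(rnorm(n * 2), n, 2)
  y <- c(1, 0, 0, 1)
  l2 <- 1e-3
  par <- sleepcast:::with_seed(2, sleepcast:::sc_lstm_init(2, 3, 2, 4))

  loss_fn <- function(pp) {
    fw <- sleepcast:::sc_lstm_forward(pp, x, scal)
    reg_loss(pp, fw$p, y, l2) + l2 * (sum(pp$Wx^2) + sum(pp$Wh^2))
  }
  fw <- sleepcast:::sc_lstm_forward(par, x, scal)
  an <- sleepcast:::sc_lstm_backward(par, x, scal, fw, y, l2)
  nu <- num_grad(loss_fn, par)
  for (k in names(par)) {
    expect_lt(max(abs(an[[k]] - nu[[k]])), 1e-5)
  }
})

test_that("both nets learn a separable sequence problem", {
  set.seed(33)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  # class 1 has a raised middle segment
  seqs <- lapply(1:n, function(i) {
    m <- matrix(rnorm(16 * 2, sd = 0.5), 16, 2)
    if (y[i] == 1) m[6:10, 1] <- m[6:10, 1] + 2
    m
  })
  scal <- matrix(0, n, 1)

  cnn <- sleepcast:::sc_cnn_fit(seqs, scal, y,
                                list(filters = 4, kernel = 4, stride = 2,
                                     hidden = 8, epochs = 30, batch = 32,
                                     lr = 0.02, l2 = 1e-4), seed = 1)
  p_cnn <- sleepcast:::sc_cnn_predict(cnn, seqs, scal)
  expect_gt(evaluate_auc(y, p_cnn), 0.95)

  lstm <- sleepcast:::sc_lstm_fit(seqs, scal, y,
                                  list(hidden = 6, dense = 8, epochs = 30,
                                       batch = 32, lr = 0.02, l2 = 1e-4),
                                  seed = 1)
  p_lstm <- sleepcast:::sc_lstm_predict(lstm, seqs, scal)
  expect_gt(evaluate_auc(y, p_lstm), 0.95)
})

test_that("seeded training is reproducible", {
  set.seed(34)
  seqs <- lapply(1:40, function(i) matrix(rnorm(12 * 2), 12, 2))
  scal <- matrix(rnorm(40 * 2), 40, 2)
  y <- rbinom(40, 1, 0.5)
  hp <- list(filters = 3, kernel = 4, stride = 2, hidden = 4, epochs = 3,
             batch = 16, lr = 0.01, l2 = 0)
  m1 <- sleepcast:::sc_cnn_fit(seqs, scal, y, hp, seed = 7)
  m2 <- sleepcast:::sc_cnn_fit(seqs, scal, y, hp, seed = 7)
  expect_identical(m1$par, m2$par)
})
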