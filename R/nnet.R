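# Minimal neural-network machinery for the benchmark's convolutional and
# recurrent classifiers: batch-vectorised forward/backward passes and Adam.
# Gradients are analytic and are verified against numerical differentiation
# in the test suite.

sc_sigmoid <- function(x) 1 / (1 + exp(-x))

sc_glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

# ---- Adam ------------------------------------------------------------------

sc_adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

sc_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- dense head: [pooled, scalars] -> relu hidden -> sigmoid ---------------

sc_head_init <- function(p_in, hidden) {
  list(W1 = sc_glorot(p_in, hidden), b1 = rep(0, hidden),
       w2 = sc_glorot(hidden, 1), b2 = 0)
}

sc_head_forward <- function(par, u) {
  a <- sweep(u %*% par$W1, 2, par$b1, `+`)
  h <- pmax(a, 0)
  s <- as.vector(h %*% par$w2) + par$b2
  list(a = a, h = h, p = sc_sigmoid(s))
}

# returns gradients for head params and d(loss)/d(u)
sc_head_backward <- function(par, u, fw, y, l2) {
  n <- length(y)
  ds <- matrix((fw$p - y) / n, ncol = 1)
  gw2 <- t(fw$h) %*% ds + 2 * l2 * par$w2
  gb2 <- sum(ds)
  dh <- ds %*% t(par$w2)
  da <- dh * (fw$a > 0)
  gW1 <- t(u) %*% da + 2 * l2 * par$W1
  gb1 <- colSums(da)
  du <- da %*% t(par$W1)
  list(grads = list(W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2), du = du)
}

sc_bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- 1-d convolution body --------------------------------------------------

# seqs: list of [steps x channels] matrices with common dimensions.
# Returns patches in t-fastest row order: row (i-1)*t_out + t.
sc_im2col <- function(seqs, kernel, stride) {
  n <- length(seqs)
  steps <- nrow(seqs[[1]])
  ch <- ncol(seqs[[1]])
  t_out <- max(1L, (steps - kernel) %/% stride + 1L)
  pat <- matrix(0, n * t_out, kernel * ch)
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    for (t in seq_len(t_out)) {
      sl <- s[seq((t - 1) * stride + 1, length.out = kernel), , drop = FALSE]
      pat[(i - 1) * t_out + t, ] <- as.vector(sl)
    }
  }
  list(patches = pat, t_out = t_out, n = n, ch = ch, kernel = kernel)
}

sc_cnn_init <- function(kc, filters, p_scalar, hidden) {
  c(list(Wc = sc_glorot(kc, filters), bc = rep(0, filters)),
    sc_head_init(2 * filters + p_scalar, hidden))
}

# forward over an im2col'd batch subset; rows_of(i) = (i-1)*t_out + (1:t_out)
sc_cnn_forward <- function(par, pat, t_out, scalars) {
  n <- nrow(scalars)
  z <- sweep(pat %*% par$Wc, 2, par$bc, `+`)
  zr <- pmax(z, 0)
  f <- ncol(zr)
  mean_pool <- matrix(0, n, f)
  max_pool <- matrix(-Inf, n, f)
  amax <- matrix(1L, n, f)
  for (t in seq_len(t_out)) {
    rows <- (seq_len(n) - 1L) * t_out + t
    zt <- zr[rows, , drop = FALSE]
    mean_pool <- mean_pool + zt
    upd <- zt > max_pool
    amax[upd] <- t
    max_pool[upd] <- zt[upd]
  }
  mean_pool <- mean_pool / t_out
  u <- cbind(mean_pool, max_pool, scalars)
  fw <- sc_head_forward(par, u)
  list(z = z, zr = zr, amax = amax, u = u, head = fw, p = fw$p)
}

sc_cnn_backward <- function(par, pat, t_out, scalars, fw, y, l2) {
  n <- nrow(scalars)
  f <- ncol(fw$amax)
  hb <- sc_head_backward(par, fw$u, fw$head, y, l2)
  du <- hb$du
  dmean <- du[, seq_len(f), drop = FALSE]
  dmax <- du[, f + seq_len(f), drop = FALSE]
  dz <- dmean[rep(seq_len(n), each = t_out), , drop = FALSE] / t_out
  for (j in seq_len(f)) {
    rows <- (seq_len(n) - 1L) * t_out + fw$amax[, j]
    dz[cbind(rows, j)] <- dz[cbind(rows, j)] + dmax[, j]
  }
  dz <- dz * (fw$z > 0)
  gWc <- t(pat) %*% dz + 2 * l2 * par$Wc
  gbc <- colSums(dz)
  c(list(Wc = gWc, bc = gbc), hb$grads)
}

# fit the convolutional classifier; seqs is a list of [steps x 2] matrices
sc_cnn_fit <- function(seqs, scalars, y, hyper, seed) {
  with_seed(seed, {
    ic <- sc_im2col(seqs, hyper$kernel, hyper$stride)
    par <- sc_cnn_init(ncol(ic$patches), hyper$filters, ncol(scalars),
                       hyper$hidden)
    st <- sc_adam_new(par)
    n <- length(y)
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = hyper$batch)) {
        idx <- ord[seq(b0, min(b0 + hyper$batch - 1, n))]
        rows <- as.vector(t(outer(idx - 1L, seq_len(ic$t_out),
                                  function(i, t) i * ic$t_out + t)))
        pat_b <- ic$patches[rows, , drop = FALSE]
        fw <- sc_cnn_forward(par, pat_b, ic$t_out,
                             scalars[idx, , drop = FALSE])
        gr <- sc_cnn_backward(par, pat_b, ic$t_out,
                              scalars[idx, , drop = FALSE], fw, y[idx],
                              hyper$l2)
        upd <- sc_adam_step(par, gr, st, hyper$lr)
        par <- upd$params
        st <- upd$state
      }
    }
    list(par = par, hyper = hyper)
  })
}

sc_cnn_predict <- function(model, seqs, scalars) {
  ic <- sc_im2col(seqs, model$hyper$kernel, model$hyper$stride)
  sc_cnn_forward(model$par, ic$patches, ic$t_out, scalars)$p
}

# ---- LSTM body -------------------------------------------------------------

sc_lstm_init <- function(ch, hidden, p_scalar, dense) {
  par <- list(Wx = sc_glorot(ch, 4 * hidden), Wh = sc_glorot(hidden, 4 * hidden),
              b = rep(0, 4 * hidden))
  # forget-gate bias starts at 1 (standard initialisation)
  par$b[hidden + seq_len(hidden)] <- 1
  c(par, sc_head_init(hidden + p_scalar, dense))
}

# x: array [steps, n, ch]
sc_lstm_forward <- function(par, x, scalars) {
  steps <- dim(x)[1]
  n <- dim(x)[2]
  hsz <- nrow(par$Wh)
  h <- matrix(0, n, hsz)
  cc <- matrix(0, n, hsz)
  cache <- vector("list", steps)
  for (t in seq_len(steps)) {
    xt <- matrix(x[t, , ], nrow = n)
    z <- sweep(xt %*% par$Wx + h %*% par$Wh, 2, par$b, `+`)
    i_g <- sc_sigmoid(z[, seq_len(hsz), drop = FALSE])
    f_g <- sc_sigmoid(z[, hsz + seq_len(hsz), drop = FALSE])
    o_g <- sc_sigmoid(z[, 2 * hsz + seq_len(hsz), drop = FALSE])
    g_g <- tanh(z[, 3 * hsz + seq_len(hsz), drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h_prev <- h
    h <- o_g * tc
    cache[[t]] <- list(xt = xt, i = i_g, f = f_g, o = o_g, g = g_g,
                       c = cc, tc = tc, c_prev = c_prev, h_prev = h_prev)
  }
  u <- cbind(h, scalars)
  fw <- sc_head_forward(par, u)
  list(cache = cache, u = u, head = fw, p = fw$p, hsz = hsz)
}

sc_lstm_backward <- function(par, x, scalars, fw, y, l2) {
  steps <- dim(x)[1]
  n <- dim(x)[2]
  hsz <- fw$hsz
  hb <- sc_head_backward(par, fw$u, fw$head, y, l2)
  dh <- hb$du[, seq_len(hsz), drop = FALSE]
  dc <- matrix(0, n, hsz)
  gWx <- par$Wx * 0
  gWh <- par$Wh * 0
  gb <- par$b * 0
  for (t in rev(seq_len(steps))) {
    ca <- fw$cache[[t]]
    do_ <- dh * ca$tc
    dc <- dc + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g
    dg <- dc * ca$i
    df <- dc * ca$c_prev
    dz <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                do_ * ca$o * (1 - ca$o),
                dg * (1 - ca$g^2))
    gWx <- gWx + t(ca$xt) %*% dz
    gWh <- gWh + t(ca$h_prev) %*% dz
    gb <- gb + colSums(dz)
    dh <- dz %*% t(par$Wh)
    dc <- dc * ca$f
  }
  c(list(Wx = gWx + 2 * l2 * par$Wx, Wh = gWh + 2 * l2 * par$Wh, b = gb),
    hb$grads)
}

# seqs list of [steps x ch] -> array [steps, n, ch]
sc_seq_array <- function(seqs) {
  steps <- nrow(seqs[[1]])
  ch <- ncol(seqs[[1]])
  arr <- array(0, c(steps, length(seqs), ch))
  for (i in seq_along(seqs)) arr[, i, ] <- seqs[[i]]
  arr
}

sc_lstm_fit <- function(seqs, scalars, y, hyper, seed) {
  with_seed(seed, {
    x <- sc_seq_array(seqs)
    par <- sc_lstm_init(dim(x)[3], hyper$hidden, ncol(scalars), hyper$dense)
    st <- sc_adam_new(par)
    n <- length(y)
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = hyper$batch)) {
        idx <- ord[seq(b0, min(b0 + hyper$batch - 1, n))]
        xb <- x[, idx, , drop = FALSE]
        fw <- sc_lstm_forward(par, xb, scalars[idx, , drop = FALSE])
        gr <- sc_lstm_backward(par, xb, scalars[idx, , drop = FALSE], fw,
                               y[idx], hyper$l2)
        upd <- sc_adam_step(par, gr, st, hyper$lr)
        par <- upd$params
        st <- upd$state
      }
    }
    list(par = par, hyper = hyper)
  })
}

sc_lstm_predict <- function(model, seqs, scalars) {
  x <- sc_seq_array(seqs)
  sc_lstm_forward(model$par, x, scalars)$p
}
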