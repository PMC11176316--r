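# Minimal neural-network engine used by the denoising autoencoder and the
# 1-D convolutional classifier. Tensors are base-R arrays: batches of
# sequences have dim (N, L, C) — sample, position, channel — and dense
# activations are (N, D) matrices. Convolutions are "valid" (no padding),
# stride 1, implemented by im2col so the inner loop is a BLAS matmul.

he_init <- function(n_in, n_out, fan_in = n_in) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan_in)), n_in, n_out)
}

relu_fwd <- function(x) pmax(x, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

activation_fwd <- function(x, kind) {
  switch(kind,
    relu = pmax(x, 0),
    sigmoid = sigmoid(x),
    identity = x,
    stop("unknown activation: ", kind)
  )
}

# derivative of the activation wrt its pre-activation, given output y
activation_bwd <- function(dy, y, kind) {
  switch(kind,
    relu = dy * (y > 0),
    sigmoid = dy * y * (1 - y),
    identity = dy,
    stop("unknown activation: ", kind)
  )
}

# ---- 1-D convolution (valid, stride 1) -------------------------------------

# x: (N, L, C_in) -> column matrix (N*L_out, K*C_in)
im2col <- function(x, kernel) {
  d <- dim(x)
  n <- d[1L]; len <- d[2L]; ch <- d[3L]
  l_out <- len - kernel + 1L
  m <- matrix(0, n * l_out, kernel * ch)
  for (k in seq_len(kernel)) {
    slab <- x[, k:(k + l_out - 1L), , drop = FALSE]    # (N, L_out, C)
    m[, ((k - 1L) * ch + 1L):(k * ch)] <- matrix(slab, n * l_out, ch)
  }
  m
}

conv1d_fwd <- function(x, w, b) {
  d <- dim(x)
  kernel <- nrow(w) / d[3L]
  l_out <- d[2L] - kernel + 1L
  m <- im2col(x, kernel)
  y2 <- sweep(m %*% w, 2L, b, "+")
  list(y = array(y2, dim = c(d[1L], l_out, ncol(w))), m = m)
}

conv1d_bwd <- function(dy, m, w, x_dim, kernel) {
  n <- x_dim[1L]; ch <- x_dim[3L]
  l_out <- x_dim[2L] - kernel + 1L
  dy2 <- matrix(dy, n * l_out, dim(dy)[3L])
  dw <- crossprod(m, dy2)
  db <- colSums(dy2)
  dm <- tcrossprod(dy2, w)
  dx <- array(0, dim = x_dim)
  for (k in seq_len(kernel)) {
    slab <- array(dm[, ((k - 1L) * ch + 1L):(k * ch)], dim = c(n, l_out, ch))
    dx[, k:(k + l_out - 1L), ] <- dx[, k:(k + l_out - 1L), , drop = FALSE] + slab
  }
  list(dx = dx, dw = dw, db = db)
}

# ---- max pooling, window 2, stride 2 (floor division) ----------------------

maxpool2_fwd <- function(x) {
  d <- dim(x)
  l_out <- d[2L] %/% 2L
  a <- x[, seq(1L, 2L * l_out, by = 2L), , drop = FALSE]
  b <- x[, seq(2L, 2L * l_out, by = 2L), , drop = FALSE]
  take_first <- a >= b            # tie -> earlier position
  list(y = pmax(a, b), take_first = take_first, l_in = d[2L])
}

maxpool2_bwd <- function(dy, take_first, l_in) {
  d <- dim(dy)
  dx <- array(0, dim = c(d[1L], l_in, d[3L]))
  dx[, seq(1L, 2L * d[2L], by = 2L), ] <- dy * take_first
  dx[, seq(2L, 2L * d[2L], by = 2L), ] <- dy * !take_first
  dx
}

# ---- batch normalization over channels of (N, L, C) ------------------------

bn_fwd <- function(x, gamma, beta, running, train, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, inv_sd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = array(y, dim = d), xhat = xhat, inv_sd = inv_sd,
       running = running)
}

bn_bwd <- function(dy, xhat, inv_sd, gamma) {
  d <- dim(dy)
  m <- d[1L] * d[2L]
  dym <- matrix(dy, m, d[3L])
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, "*")
  # standard BN backward, vectorized per channel
  t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
  t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
  dxm <- sweep(t1 - t2, 2L, inv_sd, "*")
  list(dx = array(dxm, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# ---- optimizers ------------------------------------------------------------

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_momentum_step <- function(params, grads, state, lr, momentum) {
  for (nm in names(grads)) {
    if (is.null(state$v[[nm]])) state$v[[nm]] <- grads[[nm]] * 0
    state$v[[nm]] <- momentum * state$v[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + state$v[[nm]]
  }
  list(params = params, state = state)
}

# deterministic shuffled minibatch index list
minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# binary cross-entropy with clamping; y in {0,1}, p in (0,1)
bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
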