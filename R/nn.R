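# Internal neural-network primitives for the 1-D convolutional detector.
# A batch lives as a (n_fields * n_days) x channels matrix, rows ordered
# field-major, so a temporal convolution becomes im2col + one BLAS
# matrix product per layer.

# index cache: padded-gather indices per (n_series, T, kernel)
conv_idx_cache <- new.env(parent = emptyenv())

conv_idx <- function(n, T, kernel) {
  key <- paste(n, T, kernel, sep = "x")
  hit <- conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (kernel - 1L) %/% 2L
  Tp <- T + 2L * pad              # = T + kernel - 1
  tt <- rep.int(seq_len(T), n)
  base <- rep(seq.int(0L, by = Tp, length.out = n), each = T)
  out <- list(pad = pad, Tp = Tp,
              interior = base + tt + pad,
              idx_j = lapply(seq_len(kernel), function(j)
                base + tt + (j - 1L)))
  conv_idx_cache[[key]] <- out
  out
}

# zero-pad each series in time so every kernel offset is a plain gather
pad_time <- function(xm, n, ci) {
  xp <- matrix(0, n * ci$Tp, ncol(xm))
  xp[ci$interior, ] <- xm
  xp
}

# (n*T) x cin -> (n*T) x (kernel*cin): column block j holds the input
# shifted by j-1-pad days (zero outside the season)
im2col <- function(xm, n, T, kernel) {
  ci <- conv_idx(n, T, kernel)
  C <- ncol(xm)
  xp <- pad_time(xm, n, ci)
  out <- matrix(0, n * T, kernel * C)
  for (j in seq_len(kernel))
    out[, ((j - 1L) * C + 1L):(j * C)] <- xp[ci$idx_j[[j]], ,
                                             drop = FALSE]
  out
}

# weights for the transposed convolution: the input gradient of a same-
# padded conv is another same-padded conv of the output gradient with
# the kernel flipped in time and channels transposed
flip_weights <- function(W, kernel, cin) {
  cout <- ncol(W)
  Wf <- matrix(0, kernel * cout, cin)
  for (j in seq_len(kernel)) {
    blk <- W[((kernel - j) * cin + 1L):((kernel - j + 1L) * cin), ,
             drop = FALSE]
    Wf[((j - 1L) * cout + 1L):(j * cout), ] <- t(blk)
  }
  Wf
}

glorot_uniform <- function(fan_in, fan_out, nrow, ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# activations: value and input-gradient, vectorized over matrix rows
row_max <- function(z) {
  m <- z[, 1L]
  for (j in seq_len(ncol(z))[-1L]) m <- pmax(m, z[, j])
  m
}

act_forward <- function(z, kind) {
  switch(kind,
         softmax_channel = {
           e <- exp(z - row_max(z))
           e / rowSums(e)
         },
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         linear = z,
         stop("unknown activation: ", kind))
}

act_backward <- function(dout, a, z, kind) {
  switch(kind,
         softmax_channel = a * (dout - rowSums(dout * a)),
         relu = dout * (z > 0),
         sigmoid = dout * a * (1 - a),
         tanh = dout * (1 - a^2),
         linear = dout,
         stop("unknown activation: ", kind))
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

bn_forward_train <- function(x, gamma, beta, run_mean, run_var) {
  mu <- colMeans(x)
  xc <- x - rep(mu, each = nrow(x))
  v <- colMeans(xc^2)
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(inv_sd, each = nrow(x))
  list(out = xhat * rep(gamma, each = nrow(x)) +
         rep(beta, each = nrow(x)),
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma),
       run_mean = BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu,
       run_var = BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * v)
}

bn_forward_infer <- function(x, gamma, beta, run_mean, run_var) {
  inv_sd <- 1 / sqrt(run_var + BN_EPS)
  (x - rep(run_mean, each = nrow(x))) *
    rep(gamma * inv_sd, each = nrow(x)) + rep(beta, each = nrow(x))
}

bn_backward <- function(dout, cache) {
  n <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(cache$gamma, each = n)
  dx <- (dxhat - rep(colMeans(dxhat), each = n) -
           xhat * rep(colMeans(dxhat * xhat), each = n)) *
    rep(cache$inv_sd, each = n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Nadam with Keras-style momentum schedule (schedule_decay); also plain
# Adam and SGD for the sweep harness
make_optimizer <- function(name, lr, beta_1 = 0.9, beta_2 = 0.999,
                           schedule_decay = 0.004, eps = 1e-7) {
  name <- match.arg(name, c("nadam", "adam", "sgd"))
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- state$v <- NULL
  state$m_schedule <- 1
  step <- function(params, grads) {
    state$t <- state$t + 1L
    t <- state$t
    if (is.null(state$m)) {
      state$m <- lapply(grads, function(g) g * 0)
      state$v <- lapply(grads, function(g) g * 0)
    }
    if (name == "sgd") {
      for (k in names(params))
        params[[k]] <- params[[k]] - lr * grads[[k]]
      return(params)
    }
    if (name == "nadam") {
      mu_t <- beta_1 * (1 - 0.5 * 0.96^(t * schedule_decay))
      mu_t1 <- beta_1 * (1 - 0.5 * 0.96^((t + 1) * schedule_decay))
      m_sched_new <- state$m_schedule * mu_t
      m_sched_next <- m_sched_new * mu_t1
      state$m_schedule <- m_sched_new
      for (k in names(params)) {
        g <- grads[[k]]
        g_prime <- g / (1 - m_sched_new)
        state$m[[k]] <- beta_1 * state$m[[k]] + (1 - beta_1) * g
        m_prime <- state$m[[k]] / (1 - m_sched_next)
        state$v[[k]] <- beta_2 * state$v[[k]] + (1 - beta_2) * g^2
        v_prime <- state$v[[k]] / (1 - beta_2^t)
        m_bar <- (1 - mu_t) * g_prime + mu_t1 * m_prime
        params[[k]] <- params[[k]] - lr * m_bar / (sqrt(v_prime) + eps)
      }
    } else {  # adam
      for (k in names(params)) {
        g <- grads[[k]]
        state$m[[k]] <- beta_1 * state$m[[k]] + (1 - beta_1) * g
        state$v[[k]] <- beta_2 * state$v[[k]] + (1 - beta_2) * g^2
        m_hat <- state$m[[k]] / (1 - beta_1^t)
        v_hat <- state$v[[k]] / (1 - beta_2^t)
        params[[k]] <- params[[k]] - lr * m_hat / (sqrt(v_hat) + eps)
      }
    }
    params
  }
  step
}
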