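#' Model configuration for the 1-D convolutional detector
#'
#' Three 1-D convolution layers with same-length padding map the
#' `n_days x n_features` field series to a daily mowing probability.
#' The first two convolutions are followed by the hidden activation
#' (default: softmax across the channel axis at each day) and batch
#' normalization; the third by a sigmoid. With two hidden layers of
#' kernel size `k` the output at day `d` sees days `d +/- 3*(k-1)/2`;
#' the default kernel of 9 gives a ~25-day receptive field covering the
#' 24-36-day coherence persistence of a mowing event.
#'
#' @param n_features input channels (14).
#' @param n_days season grid length (215).
#' @param conv_channels hidden channel counts for the first two layers.
#' @param kernel_size odd convolution kernel length.
#' @param hidden_activation one of `"softmax_channel"`, `"relu"`,
#'   `"sigmoid"`, `"tanh"`, `"linear"`.
#' @param optimizer `"nadam"` (default), `"adam"` or `"sgd"`.
#' @param learning_rate optimizer step size (default 1e-4).
#' @param beta_1,beta_2,schedule_decay Nadam moment parameters.
#' @param max_epochs training epoch budget (default 300).
#' @param batch_size fields per batch (default 64).
#' @param early_stopping_patience epochs without validation-loss
#'   improvement before stopping (best weights restored).
#' @param seed integer seed for initialization and batch shuffling.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_features = 14L, n_days = 215L,
                         conv_channels = c(32L, 32L), kernel_size = 9L,
                         hidden_activation = "softmax_channel",
                         optimizer = "nadam", learning_rate = 1e-4,
                         beta_1 = 0.9, beta_2 = 0.999,
                         schedule_decay = 0.004, max_epochs = 300L,
                         batch_size = 64L,
                         early_stopping_patience = 20L, seed = 1L) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  if (any(conv_channels < 1L)) stop("conv_channels must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  hidden_activation <- match.arg(
    hidden_activation,
    c("softmax_channel", "relu", "sigmoid", "tanh", "linear"))
  structure(list(n_features = as.integer(n_features),
                 n_days = as.integer(n_days),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = kernel_size,
                 hidden_activation = hidden_activation,
                 optimizer = optimizer, learning_rate = learning_rate,
                 beta_1 = beta_1, beta_2 = beta_2,
                 schedule_decay = schedule_decay,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stopping_patience =
                   as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained 1-D convolutional detector
#'
#' Initializes weights (Glorot uniform, seeded), batch-norm scales and
#' running statistics for the conv-act-BN x2 + conv-sigmoid stack.
#'
#' @param config a [model_config()].
#' @param feature_names expected input feature order; defaults to the
#'   standard 14 features when `n_features` matches, else `f1, f2, ...`.
#' @return A list of class `mow_model` with `params`, `config`,
#'   `feature_names`, `history`.
#' @export
build_model <- function(config = model_config(), feature_names = NULL) {
  if (is.null(feature_names))
    feature_names <- if (config$n_features == length(MOW_FEATURES))
      MOW_FEATURES else paste0("f", seq_len(config$n_features))
  if (length(feature_names) != config$n_features)
    stop("feature_names length must equal n_features")
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(config$seed)
  k <- config$kernel_size
  cin <- config$n_features
  c1 <- config$conv_channels[1]
  c2 <- config$conv_channels[2]
  params <- list(
    W1 = glorot_uniform(k * cin, k * c1, k * cin, c1), b1 = numeric(c1),
    g1 = rep(1, c1), be1 = numeric(c1),
    W2 = glorot_uniform(k * c1, k * c2, k * c1, c2), b2 = numeric(c2),
    g2 = rep(1, c2), be2 = numeric(c2),
    W3 = glorot_uniform(k * c2, k, k * c2, 1L), b3 = numeric(1))
  structure(list(params = params,
                 running = list(m1 = numeric(c1), v1 = rep(1, c1),
                                m2 = numeric(c2), v2 = rep(1, c2)),
                 config = config, feature_names = feature_names,
                 stats = NULL, history = NULL),
            class = "mow_model")
}

# forward pass; training mode uses batch statistics and keeps caches
nn_forward <- function(model, xm, n, T, train = FALSE) {
  p <- model$params
  k <- model$config$kernel_size
  act <- model$config$hidden_activation
  x1 <- im2col(xm, n, T, k)
  z1 <- x1 %*% p$W1 + rep(p$b1, each = n * T)
  a1 <- act_forward(z1, act)
  if (train) {
    bn1 <- bn_forward_train(a1, p$g1, p$be1,
                            model$running$m1, model$running$v1)
    h1 <- bn1$out
  } else h1 <- bn_forward_infer(a1, p$g1, p$be1,
                                model$running$m1, model$running$v1)
  x2 <- im2col(h1, n, T, k)
  z2 <- x2 %*% p$W2 + rep(p$b2, each = n * T)
  a2 <- act_forward(z2, act)
  if (train) {
    bn2 <- bn_forward_train(a2, p$g2, p$be2,
                            model$running$m2, model$running$v2)
    h2 <- bn2$out
  } else h2 <- bn_forward_infer(a2, p$g2, p$be2,
                                model$running$m2, model$running$v2)
  x3 <- im2col(h2, n, T, k)
  z3 <- drop(x3 %*% p$W3) + p$b3
  prob <- 1 / (1 + exp(-z3))
  out <- list(prob = prob)
  if (train)
    out <- c(out, list(x1 = x1, z1 = z1, a1 = a1, bn1 = bn1,
                       x2 = x2, z2 = z2, a2 = a2, bn2 = bn2, x3 = x3))
  out
}

# mean binary cross-entropy and parameter gradients for one batch
nn_backward <- function(model, fw, y, n, T) {
  p <- model$params
  k <- model$config$kernel_size
  cfg <- model$config
  act <- model$config$hidden_activation
  N <- n * T
  dz3 <- matrix((fw$prob - y) / N, ncol = 1L)
  gW3 <- crossprod(fw$x3, dz3)
  gb3 <- sum(dz3)
  dh2 <- im2col(dz3, n, T, k) %*%
    flip_weights(p$W3, k, cfg$conv_channels[2])
  bb2 <- bn_backward(dh2, fw$bn2$cache)
  dz2 <- act_backward(bb2$dx, fw$a2, fw$z2, act)
  gW2 <- crossprod(fw$x2, dz2)
  gb2 <- colSums(dz2)
  dh1 <- im2col(dz2, n, T, k) %*%
    flip_weights(p$W2, k, cfg$conv_channels[1])
  bb1 <- bn_backward(dh1, fw$bn1$cache)
  dz1 <- act_backward(bb1$dx, fw$a1, fw$z1, act)
  gW1 <- crossprod(fw$x1, dz1)
  gb1 <- colSums(dz1)
  list(W1 = gW1, b1 = gb1, g1 = bb1$dgamma, be1 = bb1$dbeta,
       W2 = gW2, b2 = gb2, g2 = bb2$dgamma, be2 = bb2$dbeta,
       W3 = gW3, b3 = gb3)
}

bce <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

# feature array (n, T, C) -> field-major (n*T) x C matrix
flatten_values <- function(values) {
  n <- dim(values)[1]; T <- dim(values)[2]; C <- dim(values)[3]
  out <- matrix(0, n * T, C)
  for (ch in seq_len(C))
    out[, ch] <- as.vector(t(values[, , ch]))
  out
}

#' Train the detector with Nadam and early stopping
#'
#' Minimizes the mean per-day binary cross-entropy over all season days.
#' After each epoch the validation loss is computed in inference mode;
#' training stops when it has not improved for
#' `early_stopping_patience` epochs and the best-epoch weights and
#' running statistics are restored.
#'
#' @param model an untrained model from [build_model()].
#' @param train_fm,val_fm `feature_matrix` objects sharing the model's
#'   feature order; `val_fm` must be non-empty.
#' @return A trained `mow_model` with `history` (per-epoch train and
#'   validation loss, best epoch) and the training `gap_stats` attached.
#' @export
train_model <- function(model, train_fm, val_fm) {
  cfg <- model$config
  if (!identical(train_fm$feature_names, model$feature_names) ||
      !identical(val_fm$feature_names, model$feature_names))
    stop("feature order mismatch between model and data")
  if (!length(val_fm$field_ids)) stop("validation split is empty")
  n_tr <- dim(train_fm$values)[1]
  T <- dim(train_fm$values)[2]
  xm_tr <- flatten_values(train_fm$values)
  y_tr <- as.vector(t(train_fm$labels))
  xm_val <- flatten_values(val_fm$values)
  y_val <- as.vector(t(val_fm$labels))
  n_val <- dim(val_fm$values)[1]

  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(cfg$seed + 1L)
  opt <- make_optimizer(cfg$optimizer, cfg$learning_rate, cfg$beta_1,
                        cfg$beta_2, cfg$schedule_decay)
  best <- list(loss = Inf, params = NULL, running = NULL, epoch = 0L)
  hist_tr <- hist_val <- numeric()

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n_tr)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      nb <- length(b)
      rows <- rep((b - 1L) * T, each = T) + rep.int(seq_len(T), nb)
      xb <- xm_tr[rows, , drop = FALSE]
      yb <- y_tr[rows]
      fw <- nn_forward(model, xb, nb, T, train = TRUE)
      loss <- bce(fw$prob, yb)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      grads <- nn_backward(model, fw, yb, nb, T)
      model$params <- opt(model$params, grads)
      model$running <- list(m1 = fw$bn1$run_mean, v1 = fw$bn1$run_var,
                            m2 = fw$bn2$run_mean, v2 = fw$bn2$run_var)
      ep_loss <- ep_loss + loss * nb
    }
    hist_tr[epoch] <- ep_loss / n_tr
    val_prob <- nn_forward(model, xm_val, n_val, T)$prob
    hist_val[epoch] <- bce(val_prob, y_val)
    if (!is.finite(hist_val[epoch]))
      stop("training diverged (non-finite validation loss) at epoch ",
           epoch)
    if (hist_val[epoch] < best$loss) {
      best <- list(loss = hist_val[epoch], params = model$params,
                   running = model$running, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$early_stopping_patience) {
      break
    }
  }
  model$params <- best$params
  model$running <- best$running
  model$stats <- train_fm$stats
  model$history <- list(train_loss = hist_tr, val_loss = hist_val,
                        best_epoch = best$epoch,
                        best_val_loss = best$loss)
  model
}

#' Daily mowing probabilities for a feature matrix
#'
#' Inference-mode forward pass (batch normalization uses running
#' statistics, so predictions are independent of batch composition).
#'
#' @param object a trained `mow_model`.
#' @param fm a `feature_matrix` with the model's feature order.
#' @param chunk fields per forward pass (memory control).
#' @param ... unused.
#' @return Matrix `n_fields x n_days` of probabilities in (0, 1), with
#'   field ids as row names.
#' @export
predict.mow_model <- function(object, fm, chunk = 256L, ...) {
  if (!identical(fm$feature_names, object$feature_names))
    stop("feature order mismatch between model and data")
  n <- dim(fm$values)[1]
  T <- dim(fm$values)[2]
  out <- matrix(NA_real_, n, T, dimnames = list(fm$field_ids, NULL))
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    xm <- flatten_values(fm$values[s:e, , , drop = FALSE])
    pr <- nn_forward(object, xm, e - s + 1L, T)$prob
    out[s:e, ] <- matrix(pr, e - s + 1L, T, byrow = TRUE)
  }
  out
}

#' @export
print.mow_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<mow_model> conv1d(%d->%d)->%s->BN -> conv1d(->%d)->%s->BN -> conv1d(->1)->sigmoid, kernel %d\n",
    cfg$n_features, cfg$conv_channels[1], cfg$hidden_activation,
    cfg$conv_channels[2], cfg$hidden_activation, cfg$kernel_size))
  if (!is.null(x$history))
    cat(sprintf("  trained: best epoch %d, val BCE %.4f\n",
                x$history$best_epoch, x$history$best_val_loss))
  else cat("  untrained\n")
  invisible(x)
}

#' Hyperparameter sweep harness
#'
#' Trains one model per setting of a grid over `{hidden_activation,
#' optimizer, learning_rate}` with a shared seed and reports event
#' accuracy, end-of-season accuracy and season-score AUC on the
#' validation split, sorted by AUC.
#'
#' @param grid a data frame with any of the columns `hidden_activation`,
#'   `optimizer`, `learning_rate`; one model per row.
#' @param train_fm,val_fm training and validation `feature_matrix`.
#' @param config base [model_config()] supplying all other settings.
#' @param eval_cfg list of decoding/evaluation settings (see
#'   [load_config()] section `eval`).
#' @return The grid with columns `event_accuracy`, `eos_accuracy`,
#'   `auc`, `val_loss` appended, sorted by decreasing `auc`.
#' @export
sweep_models <- function(grid, train_fm, val_fm,
                         config = model_config(),
                         eval_cfg = default_config()$eval) {
  if (!nrow(grid)) stop("empty sweep grid")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    for (k in intersect(names(grid),
                        c("hidden_activation", "optimizer",
                          "learning_rate")))
      cfg[[k]] <- grid[[k]][i]
    fit <- tryCatch(
      train_model(build_model(cfg), train_fm, val_fm),
      error = function(e) NULL)  # divergent settings score worst
    if (is.null(fit))
      return(data.frame(event_accuracy = NA_real_,
                        eos_accuracy = NA_real_, auc = NA_real_,
                        val_loss = Inf))
    probs <- predict(fit, val_fm)
    m <- evaluate_predictions(probs, val_fm, eval_cfg)
    data.frame(event_accuracy = m$event_accuracy,
               eos_accuracy = m$eos_accuracy, auc = m$auc,
               val_loss = fit$history$best_val_loss)
  })
  out <- cbind(grid, do.call(rbind, res))
  out[order(-out$auc, out$val_loss), , drop = FALSE]
}
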