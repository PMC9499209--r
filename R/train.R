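#' Training protocol configuration
#'
#' The optimization protocol: Adam with minibatches of 35, an "iteration"
#' comprising `epoch_size` full passes over the shuffled training set, up
#' to `max_iterations` iterations, validation binary cross-entropy
#' evaluated at the end of every iteration, and the three snapshots with
#' the lowest validation losses kept as the ensemble. No early stopping;
#' partial final minibatches are kept.
#'
#' @param minibatch Minibatch size (default 35).
#' @param epoch_size Epochs (full passes) per iteration (default 10).
#' @param max_iterations Maximum iterations (default 100).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed governing initialization and shuffling.
#' @param n_best Number of best snapshots kept (default 3).
#' @return An object of class `train_config`.
#' @export
train_config <- function(minibatch = 35L, epoch_size = 10L,
                         max_iterations = 100L, learning_rate = 1e-3,
                         seed = 1L, n_best = 3L) {
  stopifnot(minibatch >= 1L, epoch_size >= 1L, max_iterations >= 1L,
            learning_rate > 0, n_best >= 1L)
  structure(list(minibatch = as.integer(minibatch),
                 epoch_size = as.integer(epoch_size),
                 max_iterations = as.integer(max_iterations),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 n_best = as.integer(n_best)),
            class = "train_config")
}

adam_init <- function(params) {
  zero <- function(x) x * 0
  list(m = rapply(params, zero, how = "replace"),
       v = rapply(params, zero, how = "replace"), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else upd(p, g, m, v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

eval_loss <- function(model, x, y, chunk = 256L) {
  n <- dim(x)[3]
  probs <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    probs[s:e] <- cnn_forward(model, x[, , s:e, drop = FALSE])
  }
  bce_loss(probs, y)
}

#' Train the binding-site classifier
#'
#' Runs the full optimization protocol (see [train_config()]) and returns
#' the ensemble of the `n_best` snapshots with the lowest validation
#' losses. Fully reproducible for a fixed `config$seed`.
#'
#' @param x_train,y_train Training windows (`C x W x n` array) and 0/1
#'   labels.
#' @param x_val,y_val Validation windows and labels (>= 2 examples).
#' @param mconfig A [model_config()]; defaults to one matching the shape
#'   of `x_train`.
#' @param config A [train_config()].
#' @return An object of class `model_ensemble`: `members` (list of
#'   `cnn_model`s sorted by validation loss), `config` (the
#'   `model_config`), `training_meta` with the seed, iterations run, the
#'   best validation losses and the full per-iteration loss trace.
#' @export
train_cnn <- function(x_train, y_train, x_val, y_val, mconfig = NULL,
                      config = train_config()) {
  if (is.matrix(x_train)) x_train <- array(x_train, c(dim(x_train), 1L))
  if (is.matrix(x_val)) x_val <- array(x_val, c(dim(x_val), 1L))
  n <- dim(x_train)[3]
  if (n < 1L) stop("empty training set", call. = FALSE)
  if (length(y_val) < 2L)
    stop("validation set must have at least 2 examples", call. = FALSE)
  stopifnot(length(y_train) == n, dim(x_val)[3] == length(y_val),
            all(y_train %in% c(0, 1)), all(y_val %in% c(0, 1)))
  if (is.null(mconfig))
    mconfig <- model_config(in_channels = dim(x_train)[1],
                            window_len = dim(x_train)[2])
  with_seed(config$seed, {
    model <- structure(list(config = mconfig, params = init_params(mconfig)),
                       class = "cnn_model")
    state <- adam_init(model$params)
    best <- list()
    trace <- data.frame(iteration = integer(), train_loss = numeric(),
                        val_loss = numeric())
    seen <- 0L
    for (it in seq_len(config$max_iterations)) {
      batch_losses <- c()
      for (ep in seq_len(config$epoch_size)) {
        perm <- sample.int(n)
        starts <- seq(1L, n, by = config$minibatch)
        for (s in starts) {
          idx <- perm[s:min(s + config$minibatch - 1L, n)]
          xb <- x_train[, , idx, drop = FALSE]
          yb <- y_train[idx]
          fwd <- cnn_forward_full(model, xb, keep = TRUE)
          batch_losses <- c(batch_losses, bce_loss(fwd$prob, yb))
          grads <- cnn_backward(model, fwd, yb)
          stepped <- adam_step(model$params, grads, state,
                               config$learning_rate)
          model$params <- stepped$params
          state <- stepped$state
          seen <- seen + length(idx)
        }
      }
      vl <- eval_loss(model, x_val, y_val)
      trace <- rbind(trace, data.frame(iteration = it,
                                       train_loss = mean(batch_losses),
                                       val_loss = vl))
      best[[length(best) + 1L]] <- list(loss = vl, iteration = it,
                                        params = model$params)
      o <- order(vapply(best, `[[`, numeric(1), "loss"),
                 vapply(best, `[[`, numeric(1), "iteration"))
      best <- best[o[seq_len(min(config$n_best, length(best)))]]
    }
    members <- lapply(best, function(b)
      structure(list(config = mconfig, params = b$params),
                class = "cnn_model"))
    structure(list(
      members = members, config = mconfig,
      training_meta = list(
        seed = config$seed,
        iterations = config$max_iterations,
        epoch_size = config$epoch_size,
        minibatch = config$minibatch,
        learning_rate = config$learning_rate,
        examples_seen = seen,
        best_losses = vapply(best, `[[`, numeric(1), "loss"),
        best_iterations = vapply(best, `[[`, numeric(1), "iteration"),
        trace = trace)),
      class = "model_ensemble")
  })
}
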