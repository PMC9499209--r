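#' Classifier architecture configuration
#'
#' The binding-site classifier is a multi-kernel one-dimensional
#' convolutional network: for each kernel size, `filters_per_kernel`
#' same-padded convolution filters with ReLU activations produce feature
#' maps that are max-pooled across the filter axis at each base, yielding
#' one length-`W` vector per kernel size. The vectors are concatenated and
#' passed through two fully connected layers (ReLU, then sigmoid) to give
#' a binding probability. Multiple kernel sizes let the model extract
#' features at the scale of both small and large binding sites.
#'
#' @param kernel_sizes Odd convolution kernel widths (default `c(3,5,7)`).
#' @param filters_per_kernel Filters per kernel size (default 3).
#' @param in_channels Input channels `C` (default 9, the full layout).
#' @param hidden_units Width of the hidden fully connected layer
#'   (default 32).
#' @param window_len Input window length `W` (default 1000).
#' @return An object of class `model_config`.
#' @export
model_config <- function(kernel_sizes = c(3L, 5L, 7L),
                         filters_per_kernel = 3L, in_channels = 9L,
                         hidden_units = 32L, window_len = 1000L) {
  kernel_sizes <- as.integer(kernel_sizes)
  stopifnot(all(kernel_sizes %% 2L == 1L), filters_per_kernel >= 1L,
            in_channels >= 1L, hidden_units >= 1L, window_len >= 2L)
  structure(list(kernel_sizes = kernel_sizes,
                 filters_per_kernel = as.integer(filters_per_kernel),
                 in_channels = as.integer(in_channels),
                 hidden_units = as.integer(hidden_units),
                 window_len = as.integer(window_len)),
            class = "model_config")
}

# fan-in scaled uniform init, U(-1/sqrt(fanin), 1/sqrt(fanin))
init_mat <- function(nr, nc, fanin) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fanin), nr, nc)
}

#' Initialize classifier parameters
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the fan-in-scaled uniform initialization.
#' @return An object of class `cnn_model`: list with `config` and
#'   `params`. Conv weights are stored as `F x (C*k)` matrices whose
#'   column index runs channel-fastest within each kernel tap.
#' @export
init_cnn <- function(config = model_config(), seed = 1L) {
  params <- with_seed(seed, init_params(config))
  structure(list(config = config, params = params), class = "cnn_model")
}

# draws from the current RNG stream (callers control seeding)
init_params <- function(config) {
  C <- config$in_channels
  Fk <- config$filters_per_kernel
  nk <- length(config$kernel_sizes)
  W <- config$window_len
  conv <- lapply(config$kernel_sizes, function(k)
    list(W = init_mat(Fk, C * k, C * k), b = numeric(Fk)))
  names(conv) <- paste0("k", config$kernel_sizes)
  list(conv = conv,
       fc1 = list(W = init_mat(config$hidden_units, nk * W, nk * W),
                  b = numeric(config$hidden_units)),
       fc2 = list(W = init_mat(1L, config$hidden_units, config$hidden_units),
                  b = numeric(1L)))
}

# Same-padded 1D convolution of a batch, computed tap-by-tap:
# Z[f, w, b] = sum_{t, c} W[f, (t-1)C + c] * xpad[c, w + t - 1, b].
# Returns the F x (W*B) pre-activation plus the padded input (cached for
# the weight gradient). Weight columns run channel-fastest within tap.
conv1d_same <- function(x, Wmat, k) {
  d <- dim(x)
  C <- d[1]; W <- d[2]; B <- d[3]
  h <- (k - 1L) %/% 2L
  Wp <- W + k - 1L
  Fk <- nrow(Wmat)
  xf <- x
  dim(xf) <- c(C, W * B)
  Z <- matrix(0, Fk, W * B)
  for (t in seq_len(k)) {
    # per-tap feature map over all input positions, then shift-aligned:
    # output position w draws on input position w + t - 1 - h
    Yt <- Wmat[, ((t - 1L) * C + 1L):(t * C), drop = FALSE] %*% xf
    dim(Yt) <- c(Fk, W, B)
    Yp <- array(0, dim = c(Fk, Wp, B))
    Yp[, (k - t + 1L):(k - t + W), ] <- Yt
    sl <- Yp[, (h + 1L):(h + W), , drop = FALSE]
    dim(sl) <- c(Fk, W * B)
    Z <- Z + sl
  }
  list(Z = Z)
}

# gradient of the conv weights: dW[f, (t-1)C + c] = sum dZ[f,w,b] *
# xpad[c, w+t-1, b]; computed by sliding the (padded) upstream gradient
# over the raw input instead of materializing the padded input
conv1d_same_gradw <- function(dZ, x, k, C, W) {
  B <- dim(x)[3]
  h <- (k - 1L) %/% 2L
  Fk <- nrow(dZ)
  dZp <- array(0, dim = c(Fk, W + k - 1L, B))
  dZp[, (h + 1L):(h + W), ] <- dZ
  xf <- x
  dim(xf) <- c(C, W * B)
  dW <- matrix(0, Fk, C * k)
  for (t in seq_len(k)) {
    sl <- dZp[, (k - t + 1L):(k - t + W), , drop = FALSE]
    dim(sl) <- c(Fk, W * B)
    dW[, ((t - 1L) * C + 1L):(t * C)] <- tcrossprod(sl, xf)
  }
  dW
}

as_batch <- function(x, C, W) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(x)
  if (length(d) != 3L || d[1] != C || d[2] != W)
    stop("input window shape (", paste(d, collapse = "x"),
         ") does not match model config (", C, "x", W, ")", call. = FALSE)
  x
}

# full forward pass; keep = TRUE retains intermediates for backprop
cnn_forward_full <- function(model, x, keep = FALSE) {
  cfg <- model$config
  p <- model$params
  x <- as_batch(x, cfg$in_channels, cfg$window_len)
  W <- cfg$window_len
  B <- dim(x)[3]
  Fk <- cfg$filters_per_kernel
  P <- matrix(0, length(cfg$kernel_sizes) * W, B)
  cache <- list()
  for (ki in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[ki]
    pk <- p$conv[[ki]]
    cv <- conv1d_same(x, pk$W, k)
    Z <- cv$Z + pk$b                # F x (W*B); b recycles down columns
    A <- pmax(Z, 0)
    pooled <- A[1L, ]
    amax <- rep.int(1L, length(pooled))
    if (Fk > 1L) for (f in 2:Fk) {
      up <- A[f, ] > pooled
      pooled[up] <- A[f, up]
      amax[up] <- f
    }
    P[((ki - 1L) * W + 1L):(ki * W), ] <- pooled
    if (keep) cache[[ki]] <- list(Z = Z, amax = amax)
  }
  H1 <- p$fc1$W %*% P + p$fc1$b
  H <- pmax(H1, 0)
  z <- as.vector(p$fc2$W %*% H + p$fc2$b)
  prob <- sigmoid(z)
  if (!keep) return(list(prob = prob))
  list(prob = prob, P = P, H1 = H1, H = H, cache = cache, B = B, x = x)
}

#' Forward pass: binding probabilities
#'
#' @param model A `cnn_model`.
#' @param x A `C x W` window matrix or `C x W x B` batch array.
#' @return Numeric vector of probabilities strictly in (0, 1), one per
#'   window.
#' @export
cnn_forward <- function(model, x) {
  cnn_forward_full(model, x, keep = FALSE)$prob
}

# gradients of mean BCE loss wrt all parameters; fwd from
# cnn_forward_full(keep = TRUE)
cnn_backward <- function(model, fwd, y) {
  cfg <- model$config
  p <- model$params
  W <- cfg$window_len
  B <- fwd$B
  dz <- matrix((fwd$prob - y) / B, 1L, B)
  g <- list(fc2 = list(W = tcrossprod(dz, fwd$H), b = sum(dz)))
  dH <- crossprod(p$fc2$W, dz) * (fwd$H1 > 0)
  g$fc1 <- list(W = tcrossprod(dH, fwd$P), b = rowSums(dH))
  dP <- crossprod(p$fc1$W, dH)
  g$conv <- vector("list", length(cfg$kernel_sizes))
  names(g$conv) <- names(p$conv)
  Fk <- cfg$filters_per_kernel
  for (ki in seq_along(cfg$kernel_sizes)) {
    ck <- fwd$cache[[ki]]
    k <- cfg$kernel_sizes[ki]
    dpool <- as.vector(dP[((ki - 1L) * W + 1L):(ki * W), , drop = FALSE])
    dZ <- matrix(0, Fk, W * B)
    dZ[cbind(ck$amax, seq_along(dpool))] <- dpool
    dZ <- dZ * (ck$Z > 0)
    g$conv[[ki]] <- list(
      W = conv1d_same_gradw(dZ, fwd$x, k, cfg$in_channels, W),
      b = rowSums(dZ))
  }
  g
}

#' Ensemble prediction
#'
#' Arithmetic mean of the member models' binding probabilities, the
#' standard way the three best-validation-loss snapshots are combined at
#' test time.
#'
#' @param ensemble A `model_ensemble` from [train_cnn()] (or a list with
#'   a `members` list of `cnn_model`s).
#' @param x Window matrix or batch array.
#' @return Numeric vector of mean probabilities.
#' @export
predict_ensemble <- function(ensemble, x) {
  stopifnot(length(ensemble$members) >= 1L)
  probs <- vapply(ensemble$members, function(m) cnn_forward(m, x),
                  numeric(if (is.matrix(x)) 1L else dim(x)[3]))
  if (is.null(dim(probs))) return(mean(probs))
  rowMeans(probs)
}

#' Threshold binding probabilities into calls
#'
#' Sites with probability strictly greater than `constitutive_t` are
#' called `constitutive` (persistently occupied; these are also bound),
#' strictly greater than `bound_t` are `bound`, all others `unbound`.
#'
#' @param probs Numeric probabilities.
#' @param bound_t Bound-call threshold (default 0.5, strict `>`).
#' @param constitutive_t Constitutive-call threshold (default 0.95,
#'   strict `>`).
#' @return Factor with levels `c("unbound", "bound", "constitutive")`.
#' @export
threshold_calls <- function(probs, bound_t = 0.5, constitutive_t = 0.95) {
  stopifnot(bound_t > 0, bound_t < constitutive_t, constitutive_t < 1)
  out <- ifelse(probs > constitutive_t, "constitutive",
                ifelse(probs > bound_t, "bound", "unbound"))
  factor(out, levels = c("unbound", "bound", "constitutive"))
}

#' Save / load model checkpoints
#'
#' Self-describing JSON checkpoints embedding the architecture config,
#' parameters and training metadata; works for single `cnn_model`s and
#' `model_ensemble`s.
#'
#' @param obj A `cnn_model` or `model_ensemble`.
#' @param path Output `.json` file.
#' @return `path` invisibly (`save_checkpoint`); the restored object
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(obj, path) {
  ser_model <- function(m)
    list(config = unclass(m$config),
         params = rapply(m$params, as.vector, how = "replace"))
  out <- if (inherits(obj, "model_ensemble")) {
    list(format = "footprintCNN-ensemble-v1",
         members = lapply(obj$members, ser_model),
         config = unclass(obj$config),
         training_meta = obj$training_meta)
  } else {
    c(list(format = "footprintCNN-model-v1"), ser_model(obj))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

restore_params <- function(params, cfg) {
  C <- cfg$in_channels
  Fk <- cfg$filters_per_kernel
  nk <- length(cfg$kernel_sizes)
  for (ki in seq_len(nk)) {
    k <- cfg$kernel_sizes[ki]
    params$conv[[ki]]$W <- matrix(params$conv[[ki]]$W, Fk, C * k)
  }
  params$fc1$W <- matrix(params$fc1$W, cfg$hidden_units, nk * cfg$window_len)
  params$fc2$W <- matrix(params$fc2$W, 1L, cfg$hidden_units)
  params
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  de_model <- function(m) {
    cfg <- do.call(model_config, m$config[c("kernel_sizes",
      "filters_per_kernel", "in_channels", "hidden_units", "window_len")])
    structure(list(config = cfg, params = restore_params(m$params, cfg)),
              class = "cnn_model")
  }
  if (identical(raw$format, "footprintCNN-model-v1")) return(de_model(raw))
  if (identical(raw$format, "footprintCNN-ensemble-v1")) {
    members <- lapply(raw$members, de_model)
    return(structure(list(members = members,
                          config = members[[1]]$config,
                          training_meta = raw$training_meta),
                     class = "model_ensemble"))
  }
  stop("unrecognized checkpoint format", call. = FALSE)
}
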