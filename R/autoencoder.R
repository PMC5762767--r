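#' Masking corruption
#'
#' Zeroes exactly `floor(v * d)` coordinates of `x`, chosen uniformly without
#' replacement from the current RNG stream; all other coordinates are
#' returned bit-identical. This is the stochastic corruption the denoising
#' autoencoder reconstructs through.
#'
#' @param x Numeric vector in `[0, 1]^d`.
#' @param v Corruption fraction in `[0, 1]`.
#' @return The corrupted copy of `x`.
#' @export
corrupt <- function(x, v) {
  if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
    stop("corruption fraction v must be a single value in [0, 1]")
  }
  d <- length(x)
  n0 <- floor(v * d + 1e-9)
  if (n0 > 0) x[sample.int(d, n0)] <- 0
  x
}

# Mask generator shared by train_dae and its R reference loop: one column of
# zeroed indices per (epoch, instance-slot) visit.
corruption_masks <- function(d, v, m, epochs) {
  n0 <- floor(v * d + 1e-9)
  if (n0 == 0) return(matrix(integer(), nrow = 0, ncol = m * epochs))
  matrix(vapply(seq_len(m * epochs), function(i) sample.int(d, n0),
                integer(n0)), nrow = n0)
}

shuffle_orders <- function(m, epochs) {
  matrix(vapply(seq_len(epochs), function(e) sample.int(m), integer(m)),
         nrow = m)
}

#' Denoising-autoencoder parameters
#'
#' One encoder/decoder layer with tied weights: the decoder weight is always
#' the transpose of the encoder weight `W` and is never stored separately;
#' only the decoder bias `b_prime` is free. The activation is the logistic
#' sigmoid throughout.
#'
#' @param d,d_prime Input and code dimensions (`>= 1`).
#' @param W Optional `d_prime x d` weight matrix; defaults to the standard
#'   sigmoid initialization, uniform on `+/- 4 sqrt(6 / (d + d_prime))`,
#'   drawn from the current RNG stream.
#' @param b,b_prime Optional encoder/decoder biases; default zero.
#' @return An object of class `dae_params`.
#' @export
dae_params <- function(d, d_prime, W = NULL, b = NULL, b_prime = NULL) {
  stopifnot(d >= 1, d_prime >= 1)
  if (is.null(W)) {
    r <- 4 * sqrt(6 / (d + d_prime))
    W <- matrix(runif(d_prime * d, -r, r), nrow = d_prime)
  }
  stopifnot(nrow(W) == d_prime, ncol(W) == d)
  structure(list(W = W, b = b %||% numeric(d_prime),
                 b_prime = b_prime %||% numeric(d), d = as.integer(d),
                 d_prime = as.integer(d_prime)),
            class = "dae_params")
}

#' Encode through one autoencoder layer
#'
#' `y = s(W x + b)` with `s` the logistic sigmoid; outputs lie strictly in
#' `(0, 1)`. Accepts a single vector or a matrix of row vectors.
#'
#' @param p A [dae_params()].
#' @param x Numeric vector of length `d`, or an `m x d` matrix.
#' @return Code vector of length `d_prime` (or `m x d_prime` matrix).
#' @export
encode_dae <- function(p, x) {
  if (is.matrix(x)) {
    if (ncol(x) != p$d) stop("encode_dae: expected ", p$d, " columns")
    return(sigmoid(sweep(x %*% t(p$W), 2, p$b, "+")))
  }
  if (length(x) != p$d) stop("encode_dae: expected input of length ", p$d)
  sigmoid(drop(p$W %*% x) + p$b)
}

#' Decode through one autoencoder layer
#'
#' `z = s(t(W) y + b_prime)`: the tied-weight reconstruction back to the
#' input space.
#'
#' @param p A [dae_params()].
#' @param y Code vector of length `d_prime`, or an `m x d_prime` matrix.
#' @return Reconstruction of length `d` (or `m x d` matrix), strictly in
#'   `(0, 1)`.
#' @export
decode_dae <- function(p, y) {
  if (is.matrix(y)) {
    if (ncol(y) != p$d_prime) stop("decode_dae: expected ", p$d_prime,
                                   " columns")
    return(sigmoid(sweep(y %*% p$W, 2, p$b_prime, "+")))
  }
  if (length(y) != p$d_prime) {
    stop("decode_dae: expected input of length ", p$d_prime)
  }
  sigmoid(drop(crossprod(p$W, y)) + p$b_prime)
}

#' Reconstruction loss
#'
#' Squared error `sum (x - z)^2` or the cross-entropy of the Bernoulli
#' parameterization `-sum x log z + (1 - x) log(1 - z)`. Under cross-entropy
#' a reconstruction value of exactly 0 or 1 is clamped to
#' `[1e-12, 1 - 1e-12]` (with a message) so the loss stays finite.
#'
#' @param x Clean input in `[0, 1]^d`.
#' @param z Reconstruction, same length.
#' @param kind `"cross_entropy"` (default) or `"squared_error"`.
#' @return Non-negative scalar loss.
#' @export
reconstruction_loss <- function(x, z,
                                kind = c("cross_entropy", "squared_error")) {
  kind <- match.arg(kind)
  if (length(x) != length(z)) stop("x and z must have equal length")
  if (kind == "squared_error") return(sum((x - z)^2))
  eps <- 1e-12
  if (any(z <= 0 | z >= 1)) {
    message("reconstruction_loss: clamping reconstruction values to (0, 1)")
    z <- pmin(pmax(z, eps), 1 - eps)
  }
  -sum(x * log(z) + (1 - x) * log(1 - z))
}

# Reference single-instance gradient of the reconstruction loss w.r.t. the
# tied parameters, used by the finite-difference tests and by the R
# reference training loop that cross-checks the compiled path. The corrupted
# input x_tilde feeds the encoder; the loss compares against the clean x.
dae_gradients <- function(p, x, x_tilde = x,
                          kind = c("cross_entropy", "squared_error")) {
  kind <- match.arg(kind)
  y <- encode_dae(p, x_tilde)
  u <- drop(crossprod(p$W, y)) + p$b_prime
  z <- sigmoid(u)
  du <- if (kind == "squared_error") 2 * (z - x) * z * (1 - z) else z - x
  da <- drop(p$W %*% du) * y * (1 - y)
  list(W = tcrossprod(da, x_tilde) + tcrossprod(y, du),
       b = da, b_prime = du,
       loss = reconstruction_loss(x, z, kind))
}

#' Train a single denoising autoencoder layer
#'
#' One pass per epoch over the instances in a freshly shuffled order, one
#' instance at a time: corrupt the input (masking, fraction `v`), encode,
#' decode, and take a plain SGD step on the reconstruction-loss gradients
#' with the decoder gradient accumulating into the tied weight `W`. After
#' each epoch the mean reconstruction loss on the *clean* inputs is recorded.
#' Fully deterministic given `seed`.
#'
#' @param X `m x d` matrix with rows in `[0, 1]^d`.
#' @param d_prime Code dimension.
#' @param epochs Number of passes (`>= 1`).
#' @param learning_rate SGD step size (`> 0`).
#' @param loss `"cross_entropy"` (default) or `"squared_error"`.
#' @param v Corruption fraction in `[0, 1]`.
#' @param seed Integer seed controlling initialization, corruption and
#'   shuffling.
#' @return An object of class `dae` containing `params` ([dae_params()]),
#'   the per-epoch clean-input loss `trace`, and the configuration.
#' @export
train_dae <- function(X, d_prime, epochs = 10, learning_rate = 0.05,
                      loss = c("cross_entropy", "squared_error"), v = 0.3,
                      seed = 1) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, learning_rate > 0)
  if (v < 0 || v > 1) stop("corruption fraction v must be in [0, 1]")
  X <- as.matrix(X)
  m <- nrow(X); d <- ncol(X)
  p0 <- withr::with_seed(stream_seed(seed, "init"),
                         dae_params(d, d_prime))
  orders <- withr::with_seed(stream_seed(seed, "shuffle"),
                             shuffle_orders(m, epochs))
  masks <- withr::with_seed(stream_seed(seed, "corrupt"),
                            corruption_masks(d, v, m, epochs))
  fit <- dae_train_cpp(X, p0$W, p0$b, p0$b_prime, orders, masks,
                       learning_rate, if (loss == "squared_error") 0L else 1L,
                       as.integer(epochs))
  structure(
    list(params = dae_params(d, d_prime, W = fit$W, b = drop(fit$b),
                             b_prime = drop(fit$b_prime)),
         trace = drop(fit$trace),
         config = list(d_prime = d_prime, epochs = epochs,
                       learning_rate = learning_rate, loss = loss, v = v,
                       seed = seed)),
    class = "dae")
}

#' Greedy layer-wise pretraining of a stacked encoder
#'
#' Trains a stack of denoising autoencoders one layer at a time: layer 1 on
#' the raw features; its codes become the training input of layer 2, and so
#' on. Corruption is applied to each layer's *own* input. `layer_sizes[1]`
#' must equal `ncol(X)`; `layer_sizes = d` alone yields an empty stack whose
#' transform is the identity.
#'
#' @inheritParams train_dae
#' @param layer_sizes Integer vector `d, h_1, ..., h_K` of layer widths.
#' @return An object of class `stacked_encoder`: `layers` (list of
#'   [dae_params()]), `layer_sizes`, per-layer `traces`, and the config.
#' @export
pretrain_stack <- function(X, layer_sizes, epochs = 10, learning_rate = 0.05,
                           loss = c("cross_entropy", "squared_error"),
                           v = 0.3, seed = 1) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  layer_sizes <- as.integer(layer_sizes)
  if (layer_sizes[1] != ncol(X)) {
    stop("layer_sizes[1] must equal ncol(X) = ", ncol(X))
  }
  layers <- list()
  traces <- list()
  H <- X
  for (k in seq_len(length(layer_sizes) - 1L)) {
    fit <- train_dae(H, d_prime = layer_sizes[k + 1L], epochs = epochs,
                     learning_rate = learning_rate, loss = loss, v = v,
                     seed = stream_seed(seed, paste0("layer", k)))
    layers[[k]] <- fit$params
    traces[[k]] <- fit$trace
    H <- encode_dae(fit$params, H)
  }
  structure(list(layers = layers, layer_sizes = layer_sizes, traces = traces,
                 config = list(epochs = epochs,
                               learning_rate = learning_rate, loss = loss,
                               v = v, seed = seed)),
            class = "stacked_encoder")
}

#' Transform features through a stacked encoder
#'
#' Sequential clean encoding through every trained layer; no corruption is
#' applied at transform time. An empty stack returns `X` unchanged.
#'
#' @param se A [pretrain_stack()] result.
#' @param X Matrix with `ncol(X) == layer_sizes[1]`.
#' @return `m x h_K` code matrix.
#' @export
sda_transform <- function(se, X) {
  X <- as.matrix(X)
  if (ncol(X) != se$layer_sizes[1]) {
    stop("sda_transform: expected ", se$layer_sizes[1], " columns, got ",
         ncol(X))
  }
  for (p in se$layers) X <- encode_dae(p, X)
  X
}

#' @export
print.stacked_encoder <- function(x, ...) {
  cat("stacked_encoder:", paste(x$layer_sizes, collapse = " -> "), "\n")
  invisible(x)
}
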