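#' Configure the graph convolutional encoder
#'
#' Defaults are the configuration used throughout the package's experiments:
#' 2 graph-convolution layers of 16 units, ReLU activations, and 30% dropout
#' applied to the input of each layer during training.
#'
#' @param n_layers Number of graph-convolution layers.
#' @param units Output width of every layer.
#' @param dropout_rate Fraction of layer-input entries zeroed during training
#'   (inverted dropout, so eval-mode activations need no rescaling).
#' @param bias Include per-layer bias vectors? Off by default.
#' @return A `gcn_config` list.
#' @export
gcn_config <- function(n_layers = 2, units = 16, dropout_rate = 0.30,
                       bias = FALSE) {
  stopifnot(n_layers >= 1, units >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_layers = as.integer(n_layers), units = as.integer(units),
                 dropout_rate = dropout_rate, bias = isTRUE(bias)),
            class = "gcn_config")
}

# Glorot/Xavier uniform init: U(-l, l), l = sqrt(6 / (fan_in + fan_out)).
glorot_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), nrow = n_in, ncol = n_out)
}

#' Initialize GCN weights
#'
#' Draws per-layer weight matrices from a seeded Glorot-uniform scheme; the
#' shape chain runs from the input feature dimension to `units` at every
#' layer.
#'
#' @param f0 Input feature dimension (columns of the feature matrix).
#' @param config A [gcn_config()].
#' @param seed Integer seed; equal seeds give identical weights.
#' @return List of weight matrices, one per layer.
#' @export
init_gcn_params <- function(f0, config = gcn_config(), seed = NULL) {
  stopifnot(f0 >= 1)
  dims <- c(f0, rep(config$units, config$n_layers))
  run <- function() {
    map(seq_len(config$n_layers), function(i) glorot_uniform(dims[i], dims[i + 1]))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Inverted-dropout mask: entries 0 with prob `rate`, else 1/(1-rate), so the
# training-mode expectation equals the eval-mode activation.
dropout_mask <- function(n_row, n_col, rate) {
  if (rate <= 0) return(matrix(1, n_row, n_col))
  matrix(rbinom(n_row * n_col, 1L, 1 - rate) / (1 - rate), n_row, n_col)
}

#' One graph-convolution layer
#'
#' Computes `ReLU(S %*% dropout(H) %*% W)`: neighbourhood averaging through
#' the normalized propagation operator, a trainable linear map, and a ReLU.
#' Dropout hits the layer input only in training mode; eval mode is
#' deterministic.
#'
#' @param H N x F_in input activation matrix.
#' @param S Propagation operator (N x N sparse matrix or an
#'   [ot_adjacency][compute_adjacency()]).
#' @param W F_in x F_out weight matrix.
#' @param training Apply dropout?
#' @param dropout_rate Dropout rate when training.
#' @param seed Optional seed for the dropout mask.
#' @return N x F_out activation matrix.
#' @export
layer_forward <- function(H, S, W, training = FALSE, dropout_rate = 0.30,
                          seed = NULL) {
  S <- propagation_operator(S)
  if (ncol(H) != nrow(W)) {
    abort(paste0("shape mismatch: H has ", ncol(H), " columns but W has ",
                 nrow(W), " rows"))
  }
  run <- function() {
    Hd <- if (training) H * dropout_mask(nrow(H), ncol(H), dropout_rate) else H
    relu(as.matrix(S %*% Hd %*% W))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

propagation_operator <- function(S) {
  if (inherits(S, "ot_adjacency")) S$S else S
}

#' Full GCN forward pass
#'
#' Stacks [layer_forward()] calls to map node features to embeddings. With the
#' default configuration the result is a 16-dimensional embedding per node.
#'
#' @param X Feature tibble (from [node_features()]) or numeric N x F0 matrix
#'   in node-ID order.
#' @param S Propagation operator ([ot_adjacency][compute_adjacency()] or
#'   sparse matrix) over the same node order.
#' @param params Weight list from [init_gcn_params()].
#' @param config The matching [gcn_config()].
#' @param training Apply dropout at every layer input?
#' @param seed Optional seed for the dropout masks.
#' @return N x units node-embedding matrix; deterministic in eval mode.
#' @export
model_forward <- function(X, S, params, config = gcn_config(),
                          training = FALSE, seed = NULL) {
  run <- function() {
    gcn_forward_cache(as_feature_mat(X), propagation_operator(S), params,
                      config, training)$H[[config$n_layers + 1L]]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

as_feature_mat <- function(X) {
  if (is_tibble(X) || is.data.frame(X)) feature_matrix(X) else X
}

# Forward pass retaining intermediates for backprop:
#   H[[1]] = X;  for each layer i: M[[i]] dropout mask, Hd = H[[i]]*M[[i]],
#   P[[i]] = S %*% Hd (pre-weight product), Z[[i]] = P[[i]] %*% W_i,
#   H[[i+1]] = relu(Z[[i]]).
gcn_forward_cache <- function(X, S, params, config, training) {
  n_layers <- length(params)
  H <- vector("list", n_layers + 1L)
  Zs <- vector("list", n_layers)
  Ps <- vector("list", n_layers)
  Ms <- vector("list", n_layers)
  H[[1]] <- X
  for (i in seq_len(n_layers)) {
    Ms[[i]] <- if (training) {
      dropout_mask(nrow(H[[i]]), ncol(H[[i]]), config$dropout_rate)
    } else NULL
    Hd <- if (training) H[[i]] * Ms[[i]] else H[[i]]
    Ps[[i]] <- as.matrix(S %*% Hd)
    Zs[[i]] <- Ps[[i]] %*% params[[i]]
    H[[i + 1L]] <- relu(Zs[[i]])
  }
  list(H = H, Z = Zs, P = Ps, M = Ms)
}

# Backprop through the cached forward: dH_out is dL/dH[[n_layers+1]].
# Returns per-layer weight gradients (input gradients are not needed).
gcn_backward <- function(cache, S, params, dH_out, training) {
  n_layers <- length(params)
  dW <- vector("list", n_layers)
  dH <- dH_out
  for (i in rev(seq_len(n_layers))) {
    dZ <- dH * (cache$Z[[i]] > 0)
    dW[[i]] <- base::crossprod(cache$P[[i]], dZ)
    if (i > 1L) {
      dHd <- as.matrix(S %*% dZ) %*% base::t(params[[i]])  # S symmetric
      dH <- if (training) dHd * cache$M[[i]] else dHd
    }
  }
  dW
}
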