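LINK_OPERATORS <- c("hadamard", "average", "l1", "l2")

#' Combine two node embeddings into a link embedding
#'
#' Binary operators mapping a pair of node embeddings to one edge
#' representation, all symmetric in their arguments: `hadamard` (elementwise
#' product), `average`, `l1` (elementwise absolute difference) and `l2`
#' (elementwise squared difference).
#'
#' @param h_u,h_v Equal-length numeric vectors (node embeddings).
#' @param operator One of `"hadamard"`, `"average"`, `"l1"`, `"l2"`.
#' @return A numeric vector of the same length.
#' @examples
#' link_embedding(c(1, 2), c(3, 4), "hadamard")  # 3 8
#' @export
link_embedding <- function(h_u, h_v, operator = LINK_OPERATORS) {
  operator <- match.arg(operator)
  if (length(h_u) != length(h_v)) abort("embedding length mismatch")
  drop(op_embed(rbind(h_u), rbind(h_v), operator))
}

# Row-wise operator over P x d embedding matrices.
op_embed <- function(HU, HV, operator) {
  switch(operator,
    hadamard = HU * HV,
    average = (HU + HV) / 2,
    l1 = abs(HU - HV),
    l2 = (HU - HV)^2
  )
}

# Backward of op_embed: given dE (P x d), return gradients wrt HU and HV.
# l1 uses the subgradient sign(0) = 0.
op_embed_backward <- function(HU, HV, dE, operator) {
  switch(operator,
    hadamard = list(dHU = dE * HV, dHV = dE * HU),
    average = list(dHU = dE / 2, dHV = dE / 2),
    l1 = {
      s <- sign(HU - HV)
      list(dHU = dE * s, dHV = -dE * s)
    },
    l2 = {
      d <- 2 * (HU - HV)
      list(dHU = dE * d, dHV = -dE * d)
    }
  )
}

#' Initialize GCN + classification-head parameters
#'
#' GCN layer weights are Glorot-uniform ([init_gcn_params()]); the dense
#' classification head starts at zero. A zero head makes every initial link
#' probability 0.5 (maximum entropy), so the first optimizer steps learn the
#' read-out direction from the data instead of inheriting an arbitrary one —
#' with few full-batch steps, a randomly initialized head can leave scores
#' saturated along a meaningless direction that the short training run never
#' recovers from.
#'
#' @param f0 Input feature dimension.
#' @param config A [gcn_config()].
#' @param seed Integer seed.
#' @return List with `$gcn` (weight matrices) and `$head` (`w`, `b`) for the
#'   dense sigmoid classification layer.
#' @export
init_link_params <- function(f0, config = gcn_config(), seed = NULL) {
  run <- function() {
    list(gcn = init_gcn_params(f0, config),
         head = list(w = numeric(config$units), b = 0))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Score candidate links
#'
#' Applies the binary operator to the embeddings of each pair's endpoints and
#' passes the link embedding through a dense layer with a sigmoid, yielding a
#' flat vector of link probabilities.
#'
#' @param embeddings N x d node-embedding matrix in node-ID order.
#' @param pairs Tibble (or data frame) with integer columns `from`, `to`
#'   (0-based node IDs).
#' @param head List with weight vector `w` (length d) and scalar bias `b`.
#' @param operator Binary link operator, see [link_embedding()].
#' @return Numeric vector of probabilities, length `nrow(pairs)`.
#' @export
score_links <- function(embeddings, pairs, head, operator = LINK_OPERATORS) {
  operator <- match.arg(operator)
  if (any(pairs$from < 0L | pairs$from >= nrow(embeddings) |
          pairs$to < 0L | pairs$to >= nrow(embeddings))) {
    abort("pair references a node id outside the embedding matrix")
  }
  E <- op_embed(embeddings[pairs$from + 1L, , drop = FALSE],
                embeddings[pairs$to + 1L, , drop = FALSE], operator)
  plogis(drop(E %*% head$w) + head$b)
}

#' Configure link-model training
#'
#' Defaults are the training recipe used throughout: full-batch Adam at
#' learning rate 0.01 minimizing binary cross-entropy for 10 epochs, the
#' Hadamard link operator, and a 0.5 decision threshold for binary accuracy.
#'
#' @param learning_rate Adam step size.
#' @param epochs Number of full-batch epochs (one Adam step each).
#' @param operator Binary link operator, see [link_embedding()].
#' @param threshold Decision threshold for binary accuracy.
#' @param shuffle_labels Permute the training labels before fitting? Used as
#'   a negative control: a model trained on shuffled labels should score
#'   held-out links at chance (auROC about 0.5).
#' @param seed Integer seed covering initialization, dropout and any label
#'   shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 10,
                         operator = LINK_OPERATORS, threshold = 0.5,
                         shuffle_labels = FALSE, seed = NULL) {
  operator <- match.arg(operator)
  stopifnot(learning_rate > 0, epochs >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 operator = operator, threshold = threshold,
                 shuffle_labels = isTRUE(shuffle_labels), seed = seed),
            class = "train_config")
}

# Mean binary cross-entropy with clamped probabilities.
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

# Forward + loss for one parameter setting (used by training and by the
# finite-difference gradient check). Deterministic when training = FALSE.
link_loss <- function(params, X, S, pairs, labels, gcn_cfg, operator,
                      training = FALSE) {
  cache <- gcn_forward_cache(X, S, params$gcn, gcn_cfg, training)
  H_out <- cache$H[[length(params$gcn) + 1L]]
  p <- score_links(H_out, pairs, params$head, operator)
  bce_loss(p, labels)
}

# Analytic gradients of the mean BCE wrt all parameters, reusing one cached
# forward pass. Returns list(loss, scores, grads).
link_grad <- function(params, X, S, pairs, labels, gcn_cfg, operator,
                      training = FALSE) {
  cache <- gcn_forward_cache(X, S, params$gcn, gcn_cfg, training)
  H_out <- cache$H[[length(params$gcn) + 1L]]
  iu <- pairs$from + 1L
  iv <- pairs$to + 1L
  HU <- H_out[iu, , drop = FALSE]
  HV <- H_out[iv, , drop = FALSE]
  E <- op_embed(HU, HV, operator)
  logits <- drop(E %*% params$head$w) + params$head$b
  p <- plogis(logits)
  loss <- bce_loss(p, labels)

  P <- length(labels)
  dlogit <- (p - labels) / P
  d_head_w <- drop(base::crossprod(E, dlogit))
  d_head_b <- sum(dlogit)
  dE <- tcrossprod(dlogit, params$head$w)
  duv <- op_embed_backward(HU, HV, dE, operator)
  dH_out <- matrix(0, nrow(H_out), ncol(H_out))
  contrib <- rowsum(rbind(duv$dHU, duv$dHV), group = c(iu, iv))
  dH_out[as.integer(rownames(contrib)), ] <- contrib

  dW <- gcn_backward(cache, S, params$gcn, dH_out, training)
  list(loss = loss, scores = p,
       grads = list(gcn = dW, head = list(w = d_head_w, b = d_head_b)))
}

# ---- Adam optimizer over a nested parameter list ---------------------------

adam_state <- function(params) {
  zeros <- function(x) if (is.list(x)) lapply(x, zeros) else x * 0
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    m_hat <- m / (1 - beta1^state$t)
    v_hat <- v / (1 - beta2^state$t)
    list(p = p - lr * m_hat / (sqrt(v_hat) + eps), m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  out <- rec(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

#' Train the GCN link-prediction model end-to-end
#'
#' Full-batch training: embeddings are computed on the reduced training graph,
#' link probabilities on the train tier are pushed through binary
#' cross-entropy, and Adam updates all GCN and head weights, one step per
#' epoch. Dropout (on each layer's input) is active during training steps;
#' the per-epoch history and final metrics are computed in deterministic eval
#' mode. The test tier serves as the per-epoch validation set; the
#' independent tier — links never seen by the embedding graph or the
#' optimizer — provides the final auROC.
#'
#' @param split An [edge_split][split_edges()].
#' @param features Feature tibble over the full node set (see
#'   [node_features()]).
#' @param gcn_cfg A [gcn_config()].
#' @param cfg A [train_config()].
#' @return A `crispr_link_fit` with `$params`, `$history` (per-epoch tibble),
#'   `$metrics` (auROC and accuracy per tier), `$scores` (per-pair tibble) and
#'   the configurations. Supports [tidy()], [glance()] and [autoplot()].
#' @export
train_link_model <- function(split, features, gcn_cfg = gcn_config(),
                             cfg = train_config()) {
  stopifnot(inherits(split, "edge_split"))
  run <- function() train_link_model_impl(split, features, gcn_cfg, cfg)
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

train_link_model_impl <- function(split, features, gcn_cfg, cfg) {
  X <- feature_matrix(features)
  S <- compute_adjacency(split$reduced_graph)$S
  params <- init_link_params(ncol(X), gcn_cfg)

  train <- split$train
  y_train <- train$label
  if (cfg$shuffle_labels) y_train <- sample(y_train)

  eval_tier <- function(pairs, labels) {
    H <- gcn_forward_cache(X, S, params$gcn, gcn_cfg, FALSE)$H[[gcn_cfg$n_layers + 1L]]
    p <- score_links(H, pairs, params$head, cfg$operator)
    list(scores = p, loss = bce_loss(p, labels),
         acc = binary_accuracy(p, labels, cfg$threshold))
  }

  state <- adam_state(params)
  history <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    g <- link_grad(params, X, S, train, y_train, gcn_cfg, cfg$operator,
                   training = TRUE)
    if (!is.finite(g$loss)) {
      abort(paste0("non-finite training loss at epoch ", epoch))
    }
    step <- adam_step(params, g$grads, state, cfg$learning_rate)
    params <- step$params
    state <- step$state

    tr <- eval_tier(train, y_train)
    va <- eval_tier(split$test, split$test$label)
    history[[epoch]] <- tibble(
      epoch = epoch, train_loss = tr$loss, train_accuracy = tr$acc,
      val_loss = va$loss, val_accuracy = va$acc
    )
  }

  final <- map(list(train = list(p = train, y = y_train),
                    test = list(p = split$test, y = split$test$label),
                    independent = list(p = split$independent,
                                       y = split$independent$label)),
               function(t) {
                 ev <- eval_tier(t$p, t$y)
                 list(scores = ev$scores, labels = t$y, loss = ev$loss,
                      accuracy = ev$acc,
                      auroc = evaluate_auroc(ev$scores, t$y))
               })

  scores <- map_dfr(names(final), function(nm) {
    tibble(tier = nm, from = switch(nm, train = train$from,
                                    test = split$test$from,
                                    independent = split$independent$from),
           to = switch(nm, train = train$to, test = split$test$to,
                       independent = split$independent$to),
           label = final[[nm]]$labels, score = final[[nm]]$scores)
  })

  structure(list(
    params = params,
    history = bind_rows(history),
    metrics = tibble(
      tier = names(final),
      auroc = unname(map_dbl(final, "auroc")),
      accuracy = unname(map_dbl(final, "accuracy")),
      loss = unname(map_dbl(final, "loss")),
      n = unname(map_int(final, function(t) length(t$labels)))
    ),
    scores = scores,
    gcn_config = gcn_cfg,
    train_config = cfg
  ), class = "crispr_link_fit")
}

#' @export
print.crispr_link_fit <- function(x, ...) {
  ind <- x$metrics[x$metrics$tier == "independent", ]
  cat("<crispr_link_fit> ", x$gcn_config$n_layers, " GCN layers x ",
      x$gcn_config$units, " units, operator=", x$train_config$operator,
      ", ", x$train_config$epochs, " epochs\n",
      "  independent auROC ", formatC(ind$auroc, digits = 3, format = "f"),
      ", accuracy ", formatC(ind$accuracy, digits = 3, format = "f"),
      " (n=", ind$n, ")\n", sep = "")
  invisible(x)
}

#' @rdname train_link_model
#' @param x A `crispr_link_fit`.
#' @param ... Unused.
#' @method tidy crispr_link_fit
#' @export
tidy.crispr_link_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = c("set", "metric"), names_sep = "_",
                      values_to = "value")
}

#' @rdname train_link_model
#' @method glance crispr_link_fit
#' @export
glance.crispr_link_fit <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$metrics, names_from = "tier",
                             values_from = c("auroc", "accuracy", "loss", "n"))
  dplyr::bind_cols(wide, tibble(epochs = x$train_config$epochs,
                                operator = x$train_config$operator))
}
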