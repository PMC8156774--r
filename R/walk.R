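#' Configure the random-walk embedding baseline
#'
#' Second-order biased random walks with return parameter `p` and in-out
#' parameter `q`; the defaults `p = q = 1` reduce the walk to a plain uniform
#' random walk. Walk corpus sizes and the skip-gram settings are not
#' prescribed by the link-prediction protocol, so they are explicit knobs
#' recorded with every run; the embedding width defaults to 16 to match the
#' GCN embedding.
#'
#' @param walk_length Maximum walk length (nodes, including the start).
#' @param walks_per_node Walks started from every node.
#' @param p Return parameter (1/p = weight of stepping back to the previous
#'   node).
#' @param q In-out parameter (1/q = weight of stepping to a node not adjacent
#'   to the previous node).
#' @param embedding_dim Embedding width.
#' @param window Skip-gram context half-window (in walk positions).
#' @param epochs Skip-gram passes over the pair corpus.
#' @param negative Negative samples per positive pair.
#' @param learning_rate SGD step size.
#' @param seed Integer seed.
#' @return A `walk_config` list.
#' @export
walk_config <- function(walk_length = 20, walks_per_node = 10, p = 1, q = 1,
                        embedding_dim = 16, window = 5, epochs = 5,
                        negative = 5, learning_rate = 0.05, seed = NULL) {
  stopifnot(walk_length >= 1, walks_per_node >= 1, p > 0, q > 0,
            embedding_dim >= 1, window >= 1, epochs >= 1, negative >= 1)
  structure(list(walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 p = p, q = q, embedding_dim = as.integer(embedding_dim),
                 window = as.integer(window), epochs = as.integer(epochs),
                 negative = as.integer(negative),
                 learning_rate = learning_rate, seed = seed),
            class = "walk_config")
}

adjacency_list <- function(graph) {
  n <- n_nodes(graph)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    a <- e$from[k] + 1L
    b <- e$to[k] + 1L
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

#' Generate biased random walks
#'
#' Starts `walks_per_node` walks from every node and advances them by the
#' second-order rule: from current node `v` reached from `t`, the unnormalized
#' weight of neighbour `x` is `1/p` if `x == t`, `1` if `x` is adjacent to
#' `t`, and `1/q` otherwise. With `p = q = 1` every step is uniform over the
#' neighbours. Walks from isolated nodes terminate immediately (length 1).
#'
#' @param graph An [ot_graph][build_graph()].
#' @param config A [walk_config()].
#' @return A list of integer vectors of 0-based node IDs.
#' @export
generate_walks <- function(graph, config = walk_config()) {
  if (n_nodes(graph) == 0L) abort("graph is empty")
  adj <- adjacency_list(graph)
  run <- function() {
    walks <- vector("list", n_nodes(graph) * config$walks_per_node)
    w <- 0L
    for (rep in seq_len(config$walks_per_node)) {
      for (start in seq_len(n_nodes(graph))) {
        w <- w + 1L
        walks[[w]] <- one_walk(adj, start, config) - 1L
      }
    }
    walks
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

one_walk <- function(adj, start, config) {
  walk <- integer(config$walk_length)
  walk[1] <- start
  if (length(adj[[start]]) == 0L) return(walk[1])
  walk[2] <- resample(adj[[start]], 1L)
  if (config$walk_length == 1L) return(walk[1])
  for (i in seq_len(config$walk_length - 2L) + 2L) {
    t_node <- walk[i - 2L]
    v <- walk[i - 1L]
    nb <- adj[[v]]
    if (length(nb) == 0L) return(walk[seq_len(i - 1L)])
    if (config$p == 1 && config$q == 1) {
      walk[i] <- resample(nb, 1L)
    } else {
      w <- ifelse(nb == t_node, 1 / config$p,
                  ifelse(nb %in% adj[[t_node]], 1, 1 / config$q))
      walk[i] <- resample(nb, 1L, prob = w)
    }
  }
  walk
}

# sample() misbehaves on length-1 vectors; this does not.
resample <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}

#' Train skip-gram node embeddings on a walk corpus
#'
#' Skip-gram with negative sampling over (center, context) node pairs taken
#' from a window around each walk position: nodes that co-occur in short
#' walks end up close in the embedding space. Optimized by mini-batch SGD
#' (gradients aggregated per batch); negatives are drawn from the unigram
#' corpus distribution raised to the 3/4 power.
#'
#' @param walks Walk corpus from [generate_walks()].
#' @param n_nodes Total node count (embedding rows), at least
#'   `max(node id) + 1`.
#' @param config A [walk_config()].
#' @return An `n_nodes` x `embedding_dim` matrix, rows in node-ID order.
#' @export
train_walk_embeddings <- function(walks, n_nodes, config = walk_config()) {
  stopifnot(length(walks) > 0)
  run <- function() sgns_train(walks, n_nodes, config)
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

sgns_train <- function(walks, n_nodes, config) {
  pairs <- walk_pairs(walks, config$window)
  dim <- config$embedding_dim
  U <- matrix(runif(n_nodes * dim, -0.5, 0.5) / dim, n_nodes, dim)
  V <- matrix(0, n_nodes, dim)
  counts <- tabulate(unlist(walks) + 1L, nbins = n_nodes)
  neg_prob <- counts^0.75
  if (sum(neg_prob) == 0) neg_prob <- rep(1, n_nodes)
  lr <- config$learning_rate
  batch <- 1024L

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nrow(pairs))
    for (b0 in seq(1L, nrow(pairs), by = batch)) {
      idx <- ord[b0:min(b0 + batch - 1L, nrow(pairs))]
      ctr <- pairs$center[idx]
      pos <- pairs$context[idx]
      neg <- matrix(sample.int(n_nodes, length(idx) * config$negative,
                               replace = TRUE, prob = neg_prob),
                    nrow = length(idx))
      Uc <- U[ctr, , drop = FALSE]
      # positive pairs: maximize log sigmoid(u . v)
      g_pos <- plogis(rowSums(Uc * V[pos, , drop = FALSE])) - 1
      dU <- g_pos * V[pos, , drop = FALSE]
      dVpos <- g_pos * Uc
      # negatives: minimize log sigmoid(u . v_neg)
      dVneg_i <- integer(0)
      dVneg <- NULL
      for (k in seq_len(config$negative)) {
        nk <- neg[, k]
        g_neg <- plogis(rowSums(Uc * V[nk, , drop = FALSE]))
        dU <- dU + g_neg * V[nk, , drop = FALSE]
        dVneg_i <- c(dVneg_i, nk)
        dVneg <- rbind(dVneg, g_neg * Uc)
      }
      # average the accumulated gradient per node so a node that appears many
      # times in one batch still takes an O(lr) step
      updU <- rowsum(dU, ctr)
      nU <- tabulate(ctr, nbins = n_nodes)[as.integer(rownames(updU))]
      U[as.integer(rownames(updU)), ] <-
        U[as.integer(rownames(updU)), ] - lr * updU / nU
      vi <- c(pos, dVneg_i)
      updV <- rowsum(rbind(dVpos, dVneg), vi)
      nV <- tabulate(vi, nbins = n_nodes)[as.integer(rownames(updV))]
      V[as.integer(rownames(updV)), ] <-
        V[as.integer(rownames(updV)), ] - lr * updV / nV
    }
  }
  U
}

walk_pairs <- function(walks, window) {
  out <- map(walks, function(w) {
    L <- length(w)
    if (L < 2L) return(NULL)
    centers <- integer(0)
    contexts <- integer(0)
    for (i in seq_len(L)) {
      lo <- max(1L, i - window)
      hi <- min(L, i + window)
      ctx <- setdiff(lo:hi, i)
      centers <- c(centers, rep.int(w[i], length(ctx)))
      contexts <- c(contexts, w[ctx])
    }
    tibble(center = centers + 1L, context = contexts + 1L)
  })
  bind_rows(out)
}

#' Logistic-regression link classifier on node embeddings
#'
#' The baseline read-out: combine endpoint embeddings with each binary
#' operator, fit a logistic regression on the training links, and report
#' held-out auROC and accuracy per operator.
#'
#' @param embeddings N x d node-embedding matrix in node-ID order.
#' @param train_links,test_links Labeled link tibbles (`from`, `to`, `label`)
#'   from [split_edges()].
#' @param operators Operators to evaluate (default all four).
#' @return A tibble with one row per operator: `operator`, `auroc`,
#'   `accuracy`, plus a `scores` list-column of held-out probabilities.
#' @export
baseline_link_classifier <- function(embeddings, train_links, test_links,
                                     operators = LINK_OPERATORS) {
  operators <- match.arg(operators, LINK_OPERATORS, several.ok = TRUE)
  if (length(unique(train_links$label)) < 2L) {
    abort("training links contain a single class")
  }
  embed_pairs <- function(links, op) {
    op_embed(embeddings[links$from + 1L, , drop = FALSE],
             embeddings[links$to + 1L, , drop = FALSE], op)
  }
  map_dfr(operators, function(op) {
    Etr <- embed_pairs(train_links, op)
    Ete <- embed_pairs(test_links, op)
    df <- as.data.frame(Etr)
    df$.y <- train_links$label
    fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    p <- suppressWarnings(
      predict(fit, newdata = as.data.frame(Ete), type = "response")
    )
    tibble(operator = op,
           auroc = evaluate_auroc(p, test_links$label),
           accuracy = binary_accuracy(p, test_links$label),
           scores = list(unname(p)))
  })
}

#' Run the random-walk baseline end-to-end
#'
#' Generates walks on the reduced training graph, trains skip-gram
#' embeddings, and evaluates the logistic-regression link classifier on the
#' independent tier. The pipeline never reads node roles; like the GCN path
#' it sees only topology (here: walk co-occurrence).
#'
#' @param split An [edge_split][split_edges()].
#' @param config A [walk_config()].
#' @return A tibble as from [baseline_link_classifier()], tagged with a
#'   `method` column.
#' @export
walk_baseline <- function(split, config = walk_config()) {
  walks <- generate_walks(split$reduced_graph, config)
  emb <- train_walk_embeddings(walks, n_nodes(split$reduced_graph), config)
  res <- baseline_link_classifier(emb, split$train, split$independent)
  mutate(res, method = "walk_baseline")
}
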