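#' Split graph edges into train / test / independent link sets
#'
#' Implements the edge-splitting protocol of full-batch link prediction: all
#' nodes are kept in every tier; only edges are sampled. Independent-tier
#' positives are drawn first and removed, test positives next from the
#' remainder, and the surviving edges form both the reduced training graph
#' (used to compute embeddings) and the train positives. Each tier then
#' receives an equal number of negatives, sampled uniformly from unordered
#' node pairs that are not edges of the original graph and are disjoint
#' across tiers.
#'
#' @param graph An [ot_graph][build_graph()] with at least 3 edges.
#' @param independent_frac Fraction of edges held out as the independent test
#'   graph (final evaluation; never seen by embeddings or training).
#' @param test_frac Fraction of the remaining edges held out as the test set.
#' @param negative_mode `"global"` samples negatives from all non-adjacent
#'   pairs; `"bipartite"` restricts them to sgRNA-target pairs (the
#'   biologically interpretable question).
#' @param seed Optional integer seed.
#' @return An `edge_split`: `$reduced_graph` (ot_graph over the full node
#'   set), and `$train`, `$test`, `$independent` link tibbles with columns
#'   `from`, `to`, `label`.
#' @export
split_edges <- function(graph, independent_frac = 0.1, test_frac = 0.1,
                        negative_mode = c("global", "bipartite"),
                        seed = NULL) {
  negative_mode <- match.arg(negative_mode)
  stopifnot(independent_frac > 0, independent_frac < 1,
            test_frac > 0, test_frac < 1)
  m <- nrow(graph$edges)
  if (m < 3L) abort("graph must have at least 3 positive edges to split")
  n_ind <- max(1L, round(independent_frac * m))
  n_test <- max(1L, round(test_frac * (m - n_ind)))
  if (m - n_ind - n_test < 1L) {
    abort("insufficient edges for the requested split fractions")
  }
  run <- function() {
    idx <- sample.int(m)
    ind_idx <- idx[seq_len(n_ind)]
    test_idx <- idx[n_ind + seq_len(n_test)]
    train_idx <- idx[-seq_len(n_ind + n_test)]

    pos <- list(train = graph$edges[sort(train_idx), ],
                test = graph$edges[sort(test_idx), ],
                independent = graph$edges[sort(ind_idx), ])
    negs <- sample_negatives(graph, sizes = vapply(pos, nrow, integer(1)),
                             mode = negative_mode)
    tiers <- map2(pos, negs, function(p, n) {
      bind_rows(mutate(p, label = 1L), mutate(n, label = 0L))
    })
    reduced <- new_ot_graph(graph$nodes, pos$train)
    structure(list(reduced_graph = reduced,
                   train = tiers$train, test = tiers$test,
                   independent = tiers$independent,
                   independent_frac = independent_frac,
                   test_frac = test_frac,
                   negative_mode = negative_mode, seed = seed),
              class = "edge_split")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Uniform rejection sampling of unordered non-adjacent pairs, disjoint across
# tiers and never coinciding with a true edge of the full graph.
sample_negatives <- function(graph, sizes, mode) {
  n <- n_nodes(graph)
  forbidden <- new.env(hash = TRUE)
  mark <- function(from, to) {
    for (k in paste(from, to)) assign(k, TRUE, envir = forbidden)
  }
  mark(graph$edges$from, graph$edges$to)

  sgrna_ids <- graph$nodes$node_id[graph$nodes$role == "SGRNA"]
  target_ids <- graph$nodes$node_id[graph$nodes$role != "SGRNA"]

  draw_pair <- function() {
    if (mode == "bipartite") {
      c(sample(sgrna_ids, 1L), sample(target_ids, 1L))
    } else {
      sample.int(n, 2L) - 1L
    }
  }
  out <- vector("list", length(sizes))
  for (t in seq_along(sizes)) {
    from <- integer(sizes[t]); to <- integer(sizes[t])
    got <- 0L
    while (got < sizes[t]) {
      pr <- draw_pair()
      a <- min(pr); b <- max(pr)
      key <- paste(a, b)
      if (a == b || exists(key, envir = forbidden, inherits = FALSE)) next
      assign(key, TRUE, envir = forbidden)
      got <- got + 1L
      from[got] <- a; to[got] <- b
    }
    out[[t]] <- tibble(from = from, to = to)
  }
  names(out) <- names(sizes)
  out
}

#' @export
print.edge_split <- function(x, ...) {
  cat("<edge_split> train ", sum(x$train$label), "+/", sum(!x$train$label),
      "-, test ", sum(x$test$label), "+/", sum(!x$test$label),
      "-, independent ", sum(x$independent$label), "+/",
      sum(!x$independent$label), "-; ", n_nodes(x$reduced_graph),
      " nodes kept in all tiers\n", sep = "")
  invisible(x)
}
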