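new_ot_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "ot_graph")
}

#' Build the off-target sequence graph
#'
#' Every unique sequence (sgRNA and target sites, labels 1 and 0 alike)
#' becomes a node, identified by its lexicographic-rank node ID from
#' [encode_sequence_ids()]. An undirected edge joins an sgRNA to each target
#' site that induced an off-target effect (label 1); sites that never did
#' (NOT) remain isolated nodes. Roles (`SGRNA` / `OT` / `NOT`) are transient
#' bookkeeping retained on the node table for inspection, but nothing
#' downstream of graph construction reads them — prediction uses only
#' sequence-derived features and topology.
#'
#' @param records A validated off-target tibble (`sgrna`, `target`, `label`).
#' @return An `ot_graph`: `$nodes` tibble (`node_id`, `sequence`, `role`),
#'   `$edges` tibble (`from`, `to` node IDs, `from < to`), deduplicated.
#' @examples
#' rec <- generate_dataset(synthetic_config(n_sgrna = 2, seed = 1))
#' build_graph(rec)
#' @export
build_graph <- function(records) {
  both <- intersect(unique(records$sgrna), unique(records$target))
  if (length(both) > 0L) {
    abort(paste0("sequence appears both as sgRNA and as target (ambiguous role): ",
                 both[1]))
  }
  ids <- encode_sequence_ids(records)
  id_of <- setNames(ids$node_id, ids$sequence)

  target_roles <- records |>
    group_by(.data$target) |>
    summarise(role = if (any(.data$label == 1L)) "OT" else "NOT",
              .groups = "drop")
  nodes <- ids |>
    mutate(role = dplyr::case_when(
      .data$sequence %in% records$sgrna ~ "SGRNA",
      TRUE ~ target_roles$role[match(.data$sequence, target_roles$target)]
    ))

  pos <- records |> filter(.data$label == 1L)
  edges <- tibble(
    from = unname(pmin(id_of[pos$sgrna], id_of[pos$target])),
    to = unname(pmax(id_of[pos$sgrna], id_of[pos$target]))
  ) |> distinct()
  edges <- edges[order(edges$from, edges$to), ]
  new_ot_graph(nodes, edges)
}

#' @export
print.ot_graph <- function(x, ...) {
  iso <- sum(!x$nodes$node_id %in% c(x$edges$from, x$edges$to))
  cat("<ot_graph> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$role == "SGRNA"), " sgRNA, ",
      sum(x$nodes$role == "OT"), " OT, ",
      sum(x$nodes$role == "NOT"), " NOT), ",
      nrow(x$edges), " edges, ", iso, " isolated\n", sep = "")
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$nodes)

#' Per-guide cluster sampling of the NOT majority class
#'
#' Curated off-target tables are heavily imbalanced: most candidate sites
#' never cleave. Cluster data sampling rebalances each sgRNA cluster by
#' uniformly sampling its NOT records (without replacement) to a ratio of its
#' OT count, leaving every sgRNA and OT record untouched:
#'
#' * `balanced` — as many NOT as OT per cluster;
#' * `imbalanced_not` — twice as many NOT as OT;
#' * `imbalanced_ot` — `floor(n_OT / 2)` NOT per cluster.
#'
#' When a cluster holds fewer NOT records than requested, all of them are
#' kept (a shortfall is not an error).
#'
#' @param records A validated off-target tibble.
#' @param mode One of `"balanced"`, `"imbalanced_not"`, `"imbalanced_ot"`.
#' @param seed Optional integer seed for the NOT subsampling.
#' @return A tibble with the same columns; all label-1 rows, sampled label-0
#'   rows, grouped by sgRNA in first-appearance order.
#' @examples
#' rec <- generate_dataset(synthetic_config("benchmark", seed = 1))
#' table(cluster_sample(rec, "balanced", seed = 2)$label)
#' @export
cluster_sample <- function(records, mode = c("balanced", "imbalanced_not",
                                             "imbalanced_ot"),
                           seed = NULL) {
  mode <- match.arg(mode)
  run <- function() {
    records |>
      mutate(.order = row_number()) |>
      group_by(.data$sgrna) |>
      group_split() |>
      map(function(cl) {
        n_ot <- sum(cl$label == 1L)
        nots <- which(cl$label == 0L)
        want <- switch(mode,
          balanced = n_ot,
          imbalanced_not = 2L * n_ot,
          imbalanced_ot = n_ot %/% 2L
        )
        keep_not <- if (length(nots) <= want) nots else sort(sample(nots, want))
        cl[sort(c(which(cl$label == 1L), keep_not)), ]
      }) |>
      bind_rows() |>
      arrange(.data$.order) |>
      select(-".order")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Degree-normalized propagation operator
#'
#' Builds the operators a spectral graph convolution propagates through: the
#' binary symmetric adjacency matrix `A` of the (undirected) edge set, its
#' self-loop augmentation `A_hat = A + I`, and the symmetrically normalized
#' `S = D_hat^{-1/2} A_hat D_hat^{-1/2}` with `D_hat` the diagonal degree
#' matrix of `A_hat`. Self-loops ensure a node's own features enter its
#' aggregated representation; degree normalization keeps feature scales
#' stable so multiplication by `S` averages rather than sums neighbourhoods.
#' An isolated node's row of `S` is its self-loop alone (1 on the diagonal).
#'
#' @param graph An [ot_graph][build_graph()].
#' @return An `ot_adjacency` list of sparse matrices `A`, `A_hat`, `S`
#'   (all N x N, node-ID order).
#' @export
compute_adjacency <- function(graph) {
  n <- n_nodes(graph)
  e <- graph$edges
  A <- sparseMatrix(i = c(e$from, e$to) + 1L, j = c(e$to, e$from) + 1L,
                    x = 1, dims = c(n, n))
  A_hat <- A + Diagonal(n)
  d_inv_sqrt <- Diagonal(n, x = 1 / sqrt(rowSums(A_hat)))
  S <- d_inv_sqrt %*% A_hat %*% d_inv_sqrt
  structure(list(A = A, A_hat = A_hat, S = S), class = "ot_adjacency")
}

#' @export
print.ot_adjacency <- function(x, ...) {
  cat("<ot_adjacency> ", nrow(x$S), " nodes, ",
      as.integer(sum(x$A)) / 2L, " undirected edges (+ self-loops)\n", sep = "")
  invisible(x)
}

#' Graph summary counts
#'
#' @param graph An [ot_graph][build_graph()].
#' @return A one-row tibble: node, edge, role and isolated-node counts.
#' @export
graph_summary <- function(graph) {
  tibble(
    n_nodes = n_nodes(graph),
    n_edges = nrow(graph$edges),
    n_sgrna = sum(graph$nodes$role == "SGRNA"),
    n_ot = sum(graph$nodes$role == "OT"),
    n_not = sum(graph$nodes$role == "NOT"),
    n_isolated = sum(!graph$nodes$node_id %in%
                       c(graph$edges$from, graph$edges$to))
  )
}
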