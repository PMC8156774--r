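test_that("build_graph wires sgRNA-OT edges and isolates NOT nodes", {
  g1 <- generate_sgrna(1, seed = 1)
  rec <- tibble::tibble(
    sgrna = g1,
    target = vapply(1:5, function(i) mutate_target(g1, 2, seed = i),
                    character(1)),
    label = c(1L, 1L, 0L, 0L, 0L)
  )
  g <- build_graph(rec)
  expect_identical(nrow(g$nodes), 6L)
  expect_identical(nrow(g$edges), 2L)
  s <- graph_summary(g)
  expect_identical(s$n_isolated, 3L)
  expect_identical(s$n_sgrna, 1L)
  # every edge joins the sgRNA node and an OT node
  roles <- g$nodes$role[match(c(g$edges$from, g$edges$to), g$nodes$node_id)]
  expect_setequal(roles, c("SGRNA", "OT"))
})

test_that("a shared OT target becomes one node with two edges", {
  gs <- generate_sgrna(2, seed = 2)
  shared <- mutate_target(gs[1], 2, seed = 3)
  rec <- tibble::tibble(sgrna = rep(gs, each = 1), target = shared,
                        label = 1L)
  g <- build_graph(rec)
  expect_identical(sum(g$nodes$role == "OT"), 1L)
  expect_identical(nrow(g$edges), 2L)
})

test_that("all-negative records give an edgeless graph; ambiguous roles error", {
  rec <- toy_records()
  rec0 <- dplyr::mutate(rec, label = 0L)
  expect_identical(nrow(build_graph(rec0)$edges), 0L)

  bad <- rec
  bad$target[1] <- bad$sgrna[2]
  expect_error(build_graph(bad), "both as sgRNA and as target")
})

test_that("cluster_sample keeps sgRNA/OT records intact in every mode", {
  rec <- generate_dataset(synthetic_config(n_sgrna = 6, ot_per_cluster = 4,
                                           not_per_cluster = 10, seed = 7))
  for (mode in c("balanced", "imbalanced_not", "imbalanced_ot")) {
    out <- cluster_sample(rec, mode, seed = 1)
    expect_identical(out[out$label == 1L, ], rec[rec$label == 1L, ])
    want <- switch(mode, balanced = 4L, imbalanced_not = 8L,
                   imbalanced_ot = 2L)
    counts <- table(out$sgrna[out$label == 0L])
    expect_true(all(counts == want))
  }
})

test_that("cluster_sample follows the per-cluster ratio rules and shortfalls", {
  g1 <- generate_sgrna(1, seed = 4)
  rec <- tibble::tibble(
    sgrna = g1,
    target = vapply(1:14, function(i) mutate_target(g1, 3, seed = 100 + i),
                    character(1)),
    label = rep(c(1L, 0L), c(4L, 10L))
  )
  expect_identical(sum(cluster_sample(rec, "balanced", seed = 1)$label == 0L), 4L)
  expect_identical(sum(cluster_sample(rec, "imbalanced_not", seed = 1)$label == 0L), 8L)
  expect_identical(sum(cluster_sample(rec, "imbalanced_ot", seed = 1)$label == 0L), 2L)
  # shortfall: only 3 NOT available but 8 requested -> keep all 3
  short <- rec[c(1:4, 5:7), ]
  expect_identical(sum(cluster_sample(short, "imbalanced_not", seed = 1)$label == 0L), 3L)
})

test_that("sampling touches only NOT records, so the edge set is unchanged", {
  rec <- generate_dataset(synthetic_config(n_sgrna = 5, seed = 13))
  e_full <- build_graph(rec)$edges
  e_samp <- build_graph(cluster_sample(rec, "balanced", seed = 2))$edges
  # node ids differ (fewer nodes) so compare by sequence pairs
  seq_pairs <- function(rec) {
    pos <- rec[rec$label == 1L, ]
    sort(paste(pos$sgrna, pos$target))
  }
  expect_identical(seq_pairs(cluster_sample(rec, "balanced", seed = 2)[
    cluster_sample(rec, "balanced", seed = 2)$label == 1L, ]),
    seq_pairs(rec))
  expect_identical(nrow(e_samp), nrow(e_full))
})

test_that("propagation operator matches hand and dense-eigen oracles", {
  # two nodes, one edge: S = [[0.5, 0.5], [0.5, 0.5]]
  nodes <- tibble::tibble(node_id = 0:1, sequence = c("a", "b"),
                          role = c("SGRNA", "OT"))
  edges <- tibble::tibble(from = 0L, to = 1L)
  S2 <- compute_adjacency(crisprlink:::new_ot_graph(nodes, edges))$S
  expect_equal(as.matrix(S2), matrix(0.5, 2, 2), ignore_attr = TRUE)

  # isolated node: row is self-loop only
  nodes3 <- tibble::tibble(node_id = 0:2, sequence = c("a", "b", "c"),
                           role = c("SGRNA", "OT", "NOT"))
  A3 <- compute_adjacency(crisprlink:::new_ot_graph(nodes3, edges))
  expect_equal(as.matrix(A3$S)[3, ], c(0, 0, 1), ignore_attr = TRUE)
  expect_true(all(Matrix::diag(A3$A_hat) == 1))

  # star sgRNA + 2 OT: symmetric, spectrum within [-1, 1]
  star <- crisprlink:::new_ot_graph(
    tibble::tibble(node_id = 0:2, sequence = c("g", "t1", "t2"),
                   role = c("SGRNA", "OT", "OT")),
    tibble::tibble(from = c(0L, 0L), to = c(1L, 2L))
  )
  S <- as.matrix(compute_adjacency(star)$S)
  expect_equal(S, t(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev <= 1 + 1e-12 & ev >= -1 - 1e-12))
})

test_that("S equals the dense reference and stays bounded on random graphs", {
  withr::with_seed(31, {
    for (i in 1:10) {
      fx <- random_graph_fixture(sample(5:40, 1), sample(4:60, 1))
      S <- as.matrix(compute_adjacency(fx$graph)$S)
      expect_equal(S, dense_propagation(fx$graph), tolerance = 1e-12,
                   ignore_attr = TRUE)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(abs(ev) <= 1 + 1e-10))
    }
  })
})
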