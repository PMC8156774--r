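two_clique_graph <- function(k = 6) {
  # two disconnected k-cliques: nodes 0..k-1 and k..2k-1
  pairs <- rbind(t(combn(0:(k - 1), 2)), t(combn(k:(2 * k - 1), 2)))
  crisprlink:::new_ot_graph(
    tibble::tibble(node_id = 0:(2 * k - 1),
                   sequence = paste0("n", 0:(2 * k - 1)), role = "OT"),
    tibble::tibble(from = pairs[, 1], to = pairs[, 2])
  )
}

test_that("walks start everywhere, stop at isolated nodes, alternate on an edge", {
  nodes <- tibble::tibble(node_id = 0:2, sequence = c("a", "b", "c"),
                          role = c("SGRNA", "OT", "NOT"))
  g <- crisprlink:::new_ot_graph(nodes, tibble::tibble(from = 0L, to = 1L))
  cfg <- walk_config(walk_length = 10, walks_per_node = 2, seed = 1)
  walks <- generate_walks(g, cfg)
  expect_length(walks, 6)
  starts <- vapply(walks, `[`, integer(1), 1)
  expect_identical(sort(unique(starts)), 0:2)
  # isolated node 2: walk is itself alone
  expect_true(all(lengths(walks[starts == 2]) == 1))
  # single edge: forced alternation
  for (w in walks[starts %in% 0:1]) {
    expect_identical(w, rep(c(w[1], 1L - w[1]), length.out = 10))
  }
  expect_identical(generate_walks(g, cfg), walks)
})

test_that("p = q = 1 transitions are uniform over neighbours (triangle graph)", {
  tri <- crisprlink:::new_ot_graph(
    tibble::tibble(node_id = 0:2, sequence = c("a", "b", "c"), role = "OT"),
    tibble::tibble(from = c(0L, 0L, 1L), to = c(1L, 2L, 2L))
  )
  walks <- generate_walks(tri, walk_config(walk_length = 50,
                                           walks_per_node = 60, seed = 2))
  # count transitions out of node 0
  from0 <- unlist(lapply(walks, function(w) {
    i <- which(w[-length(w)] == 0)
    w[i + 1]
  }))
  frac1 <- mean(from0 == 1)
  expect_equal(frac1, 0.5, tolerance = 0.05)

  # second-order rule with p = q = 1 equals first-order uniform statistics
  biased <- generate_walks(tri, walk_config(walk_length = 50,
                                            walks_per_node = 60, p = 1, q = 1,
                                            seed = 2))
  expect_identical(biased, walks)
})

test_that("strong p/q bias shifts return behaviour in the expected direction", {
  tri <- crisprlink:::new_ot_graph(
    tibble::tibble(node_id = 0:2, sequence = c("a", "b", "c"), role = "OT"),
    tibble::tibble(from = c(0L, 0L, 1L), to = c(1L, 2L, 2L))
  )
  returny <- generate_walks(tri, walk_config(walk_length = 30,
                                             walks_per_node = 40,
                                             p = 0.01, q = 100, seed = 3))
  return_rate <- function(walks) {
    steps <- unlist(lapply(walks, function(w) {
      if (length(w) < 3) return(NULL)
      w[3:length(w)] == w[1:(length(w) - 2)]
    }))
    mean(steps)
  }
  uniform <- generate_walks(tri, walk_config(walk_length = 30,
                                             walks_per_node = 40, seed = 3))
  expect_gt(return_rate(returny), return_rate(uniform))
})

test_that("skip-gram embeddings separate two cliques; shapes and seeds hold", {
  g <- two_clique_graph(6)
  cfg <- walk_config(walk_length = 12, walks_per_node = 8,
                     embedding_dim = 8, epochs = 3, seed = 4)
  walks <- generate_walks(g, cfg)
  emb <- train_walk_embeddings(walks, 12, cfg)
  expect_identical(dim(emb), c(12L, 8L))
  expect_identical(train_walk_embeddings(walks, 12, cfg), emb)

  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  within <- c(combn(1:6, 2, function(p) cos(emb[p[1], ], emb[p[2], ])),
              combn(7:12, 2, function(p) cos(emb[p[1], ], emb[p[2], ])))
  between <- as.vector(outer(1:6, 7:12,
                             Vectorize(function(i, j) cos(emb[i, ], emb[j, ]))))
  expect_gt(mean(within), mean(between))
})

test_that("baseline classifier: separable links, shuffled control, four operators", {
  withr::with_seed(8, {
    # linearly separable link embeddings by construction: class-coded features
    emb <- rbind(matrix(2, 10, 4) + matrix(rnorm(40, sd = 0.1), 10),
                 matrix(-2, 10, 4) + matrix(rnorm(40, sd = 0.1), 10))
    links <- tibble::tibble(
      from = c(0:4, 10:14), to = c(5:9, 15:19),
      label = rep(c(1L, 0L), each = 5)
    )
    res <- baseline_link_classifier(emb, links, links, operators = "average")
    expect_equal(res$auroc, 1.0)

    # all four operators reported
    res4 <- baseline_link_classifier(emb, links, links)
    expect_identical(res4$operator, c("hadamard", "average", "l1", "l2"))

    expect_error(
      baseline_link_classifier(emb, dplyr::mutate(links, label = 1L), links),
      "single class"
    )

    # shuffled training labels -> chance-level auROC on held-out links
    held_out <- tibble::tibble(
      from = c(0:4, 10:14), to = c(9:5, 19:15),
      label = rep(c(1L, 0L), each = 5)
    )
    aucs <- vapply(1:12, function(i) {
      sh <- dplyr::mutate(links, label = sample(label))
      baseline_link_classifier(emb, sh, held_out, operators = "average")$auroc
    }, numeric(1))
    expect_gt(mean(aucs), 0.25)
    expect_lt(mean(aucs), 0.75)
  })
})

test_that("walk_baseline runs end-to-end on a split graph", {
  rec <- generate_dataset(synthetic_config(n_sgrna = 4, ot_per_cluster = 10,
                                           not_per_cluster = 10, seed = 31))
  g <- build_graph(cluster_sample(rec, "balanced", seed = 1))
  sp <- split_edges(g, seed = 2)
  res <- walk_baseline(sp, walk_config(walk_length = 10, walks_per_node = 4,
                                       epochs = 2, seed = 3))
  expect_identical(nrow(res), 4L)
  expect_true(all(res$auroc >= 0 & res$auroc <= 1))
  expect_identical(unique(res$method), "walk_baseline")
})
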