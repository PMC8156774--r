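test_that("auROC matches brute-force pair counting and its contracts", {
  expect_equal(evaluate_auroc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_equal(evaluate_auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # frozen hand example: pairs (0.8>0.3), (0.8>0.2) wait-ordered brute force
  expect_equal(evaluate_auroc(c(0.9, 0.8, 0.3, 0.2), c(0, 1, 0, 1)), 0.25)
  expect_error(evaluate_auroc(c(0.1, 0.2), c(1, 1)), "at least one")

  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(4:40, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
      expect_equal(evaluate_auroc(scores, labels),
                   auroc_bruteforce(scores, labels))
      # antisymmetry
      expect_equal(evaluate_auroc(-scores, labels),
                   1 - evaluate_auroc(scores, labels))
    }
  })
})

test_that("auROC agrees with pROC on random inputs", {
  skip_if_not_installed("pROC")
  withr::with_seed(6, {
    for (i in 1:10) {
      n <- sample(10:100, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- runif(n)
      ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                                   direction = "<")))
      expect_equal(evaluate_auroc(scores, labels), ref)
    }
  })
})

test_that("split_edges conserves nodes and edges across disjoint tiers", {
  rec <- generate_dataset(synthetic_config(n_sgrna = 5, ot_per_cluster = 10,
                                           not_per_cluster = 12, seed = 2))
  g <- build_graph(rec)
  sp <- split_edges(g, independent_frac = 0.1, test_frac = 0.1, seed = 4)
  expect_identical(nrow(sp$reduced_graph$nodes), nrow(g$nodes))

  key <- function(d) paste(d$from, d$to)
  pos <- list(train = sp$train[sp$train$label == 1, ],
              test = sp$test[sp$test$label == 1, ],
              independent = sp$independent[sp$independent$label == 1, ])
  # positives partition the original edge set
  expect_setequal(unlist(lapply(pos, key)), key(g$edges))
  expect_identical(sum(vapply(pos, nrow, integer(1))), nrow(g$edges))
  expect_identical(key(sp$reduced_graph$edges), key(pos$train))

  # tier sizes follow the stated fractions of the actual edge count
  m <- nrow(g$edges)
  n_ind <- max(1L, as.integer(round(0.1 * m)))
  n_test <- max(1L, as.integer(round(0.1 * (m - n_ind))))
  expect_identical(nrow(pos$independent), n_ind)
  expect_identical(nrow(pos$test), n_test)
  expect_identical(nrow(pos$train), m - n_ind - n_test)

  # equal negatives per tier; negatives disjoint and never true edges
  negs <- list(sp$train[sp$train$label == 0, ],
               sp$test[sp$test$label == 0, ],
               sp$independent[sp$independent$label == 0, ])
  expect_identical(vapply(negs, nrow, integer(1)),
                   vapply(pos, nrow, integer(1), USE.NAMES = FALSE))
  all_neg <- unlist(lapply(negs, key))
  expect_identical(anyDuplicated(all_neg), 0L)
  expect_length(intersect(all_neg, key(g$edges)), 0)
})

test_that("bipartite negative sampling only pairs sgRNA with targets", {
  rec <- generate_dataset(synthetic_config(n_sgrna = 4, ot_per_cluster = 8,
                                           not_per_cluster = 8, seed = 3))
  g <- build_graph(rec)
  sp <- split_edges(g, negative_mode = "bipartite", seed = 9)
  sg <- g$nodes$node_id[g$nodes$role == "SGRNA"]
  negs <- dplyr::bind_rows(sp$train, sp$test, sp$independent) |>
    dplyr::filter(label == 0)
  expect_true(all(xor(negs$from %in% sg, negs$to %in% sg)))
})

test_that("link operators match definitions and are symmetric", {
  expect_equal(link_embedding(c(1, 2), c(3, 4), "hadamard"), c(3, 8))
  expect_equal(link_embedding(c(1, 2), c(3, 4), "average"), c(2, 3))
  expect_equal(link_embedding(c(1, 2), c(3, 4), "l1"), c(2, 2))
  expect_equal(link_embedding(c(1, 2), c(3, 4), "l2"), c(4, 4))
  for (op in c("hadamard", "average", "l1", "l2")) {
    u <- rnorm(8); v <- rnorm(8)
    expect_equal(link_embedding(u, v, op), link_embedding(v, u, op))
  }
  expect_error(link_embedding(1:2, 1:3, "l1"), "length mismatch")
})

test_that("score_links is the sigmoid of a dense layer over link embeddings", {
  emb <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)  # node 0: (1,2); node 1: (3,4)
  pairs <- tibble::tibble(from = 0L, to = 1L)
  expect_equal(score_links(emb, pairs, list(w = c(0, 0), b = 0), "hadamard"),
               0.5)
  # hand calculation: hadamard (3,8), w=(0.1,-0.2), b=0.3 -> logit -1.0
  expect_equal(score_links(emb, pairs, list(w = c(0.1, -0.2), b = 0.3),
                           "hadamard"),
               plogis(-1))
  # monotone in the logit
  expect_gt(score_links(emb, pairs, list(w = c(0.2, -0.2), b = 0.3), "hadamard"),
            score_links(emb, pairs, list(w = c(0.1, -0.2), b = 0.3), "hadamard"))
  expect_error(score_links(emb, tibble::tibble(from = 0L, to = 5L),
                           list(w = c(0, 0), b = 0)), "outside")
})

test_that("analytic gradients match central finite differences (all operators)", {
  fx <- five_node_fixture()
  cfg <- gcn_config(dropout_rate = 0)
  for (op in c("hadamard", "average", "l1", "l2")) {
    params <- init_link_params(4, cfg, seed = 31)
    params$head$w <- withr::with_seed(32, runif(16, -0.3, 0.3))
    an <- crisprlink:::link_grad(params, fx$X, fx$S, fx$pairs, fx$labels,
                                 cfg, op)
    ana <- flatten_params(list(gcn = an$grads$gcn, head = an$grads$head))
    num <- numeric_link_grad(params, fx$X, fx$S, fx$pairs, fx$labels, cfg, op)
    rel <- max(abs(ana - num) / pmax(abs(num), 1e-6))
    expect_lt(rel, 1e-4)
  }
})

test_that("training reduces loss on separable data; epochs = 0 is a no-op", {
  rec <- generate_dataset(synthetic_config(n_sgrna = 4, ot_per_cluster = 10,
                                           not_per_cluster = 10,
                                           ot_mismatch_range = 1:2,
                                           not_mismatch_range = 5:6,
                                           seed = 17))
  g <- withr::with_seed(1, build_graph(cluster_sample(rec, "balanced")))
  feats <- node_features(g, "kmer-1")
  sp <- split_edges(g, seed = 2)

  fit0 <- train_link_model(sp, feats, cfg = train_config(epochs = 0, seed = 3))
  ref <- withr::with_seed(3, init_link_params(4, gcn_config()))
  expect_identical(fit0$params, ref)
  expect_identical(nrow(fit0$history), 0L)

  fit <- train_link_model(sp, feats, cfg = train_config(seed = 3))
  init_loss <- crisprlink:::link_loss(
    ref, feature_matrix(feats), compute_adjacency(sp$reduced_graph)$S,
    sp$train, sp$train$label, gcn_config(), "hadamard"
  )
  expect_lt(dplyr::last(fit$history$train_loss), init_loss)
  expect_identical(nrow(fit$history), 10L)
  expect_true(all(fit$scores$score >= 0 & fit$scores$score <= 1))
  # same seed, same result
  fit2 <- train_link_model(sp, feats, cfg = train_config(seed = 3))
  expect_identical(fit2$metrics, fit$metrics)
})

test_that("tidy, glance and plots expose the fit", {
  rec <- generate_dataset(synthetic_config(n_sgrna = 4, ot_per_cluster = 8,
                                           not_per_cluster = 8, seed = 23))
  fit <- run_link_experiment(rec, "kmer-1", "balanced", seed = 5)
  td <- tidy(fit)
  expect_setequal(unique(td$metric), c("loss", "accuracy"))
  expect_identical(nrow(td), 10L * 4L)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("auroc_independent", "auroc_test") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_roc(fit), "ggplot")
})

test_that("the experiment grid covers scheme x mode cells within [0, 1]", {
  rec <- generate_dataset(synthetic_config(n_sgrna = 4, ot_per_cluster = 8,
                                           not_per_cluster = 16, seed = 29))
  grid <- run_experiment_grid(rec, schemes = c("kmer-1", "positional"),
                              modes = c("balanced", "imbalanced_not"),
                              seeds = 1:2)
  expect_identical(nrow(grid), 4L)
  expect_true(all(grid$auroc_independent >= 0 & grid$auroc_independent <= 1))
  expect_true(all(grid$n_seeds == 2L))
  # averaging identical seeds equals the single seed
  g1 <- run_experiment_grid(rec, "kmer-1", "balanced", seeds = 1)
  g11 <- run_experiment_grid(rec, "kmer-1", "balanced", seeds = c(1, 1))
  expect_equal(g1$auroc_independent, g11$auroc_independent)
  expect_s3_class(plot_grid_auroc(grid), "ggplot")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(grid, tf)
  expect_identical(nrow(readr::read_tsv(tf, show_col_types = FALSE)), 2L)
})
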