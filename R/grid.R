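FEATURE_SCHEMES <- c("kmer-1", "kmer-2", "kmer-3", "positional")
BALANCE_MODES <- c("balanced", "imbalanced_not", "imbalanced_ot")

#' One end-to-end link-prediction run
#'
#' Samples the clusters, builds the graph, featurizes, splits the edges and
#' trains the GCN link model, all under one seed, so a run is fully
#' reproducible from `(records, scheme, mode, seed)`.
#'
#' @inheritParams run_experiment_grid
#' @param scheme Feature scheme (see [node_features()]).
#' @param mode Cluster-sampling mode (see [cluster_sample()]).
#' @param seed Integer seed covering sampling, splitting and training.
#' @return A `crispr_link_fit`, see [train_link_model()].
#' @export
run_link_experiment <- function(records, scheme, mode, seed,
                                independent_frac = 0.1, test_frac = 0.1,
                                negative_mode = "global",
                                gcn_cfg = gcn_config(), cfg = train_config()) {
  withr::with_seed(seed, {
    sampled <- cluster_sample(records, mode)
    graph <- build_graph(sampled)
    feats <- node_features(graph, scheme)
    split <- split_edges(graph, independent_frac = independent_frac,
                         test_frac = test_frac, negative_mode = negative_mode)
    train_link_model(split, feats, gcn_cfg, cfg)
  })
}

#' Run the feature-scheme by balance-mode experiment grid
#'
#' For every combination of feature scheme (`kmer-1`, `kmer-2`, `kmer-3`,
#' `positional`) and cluster-sampling mode (`balanced`, `imbalanced_not`,
#' `imbalanced_ot`), and for every seed: sample the clusters, build the
#' graph, featurize, split the edges, train the GCN link model and evaluate.
#' Because the NOT records are randomly subsampled, single runs vary; the
#' grid therefore averages auROC over the seeds.
#'
#' @param records A validated off-target tibble.
#' @param schemes Feature schemes to run (default all four).
#' @param modes Cluster-sampling modes to run (default all three).
#' @param seeds Integer vector; each seed drives one full run of every cell.
#' @param per_seed Return one row per (cell, seed) instead of cell means?
#' @inheritParams split_edges
#' @param gcn_cfg,cfg Model and training configuration shared by all cells.
#' @return A tibble with `scheme`, `mode` and mean `auroc_independent`,
#'   `auroc_test`, `accuracy_independent` over seeds (or per-seed rows when
#'   `per_seed = TRUE`).
#' @export
run_experiment_grid <- function(records, schemes = FEATURE_SCHEMES,
                                modes = BALANCE_MODES, seeds = 1:3,
                                per_seed = FALSE,
                                independent_frac = 0.1, test_frac = 0.1,
                                negative_mode = "global",
                                gcn_cfg = gcn_config(), cfg = train_config()) {
  schemes <- match.arg(schemes, FEATURE_SCHEMES, several.ok = TRUE)
  modes <- match.arg(modes, BALANCE_MODES, several.ok = TRUE)
  cells <- tidyr::expand_grid(scheme = schemes, mode = modes, seed = seeds)
  rows <- pmap(cells, function(scheme, mode, seed) {
    fit <- run_link_experiment(records, scheme, mode, seed,
                               independent_frac, test_frac, negative_mode,
                               gcn_cfg, cfg)
    m <- fit$metrics
    tibble(
      scheme = scheme, mode = mode, seed = seed,
      auroc_independent = m$auroc[m$tier == "independent"],
      auroc_test = m$auroc[m$tier == "test"],
      accuracy_independent = m$accuracy[m$tier == "independent"]
    )
  })
  out <- bind_rows(rows)
  if (per_seed) return(out)
  out |>
    group_by(.data$scheme, .data$mode) |>
    summarise(across(c("auroc_independent", "auroc_test",
                       "accuracy_independent"), mean),
              n_seeds = dplyr::n(), .groups = "drop")
}

#' Write a grid-result table as TSV
#'
#' Rows are feature schemes, columns the three balance modes, cells the mean
#' independent-tier auROC.
#'
#' @param grid Output of [run_experiment_grid()].
#' @param path Output TSV path.
#' @return `grid`, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  wide <- tidyr::pivot_wider(
    grid[, c("scheme", "mode", "auroc_independent")],
    names_from = "mode", values_from = "auroc_independent"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(grid)
}
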