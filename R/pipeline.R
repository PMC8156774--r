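#' Describe a full link-prediction run
#'
#' A `run_config` captures everything needed to reproduce a run: the input
#' (file path or synthetic preset), feature scheme, cluster-sampling mode,
#' split fractions, model and training settings, and the seed. It is plain
#' data and serializes to JSON, so a stored config reproduces its run
#' exactly.
#'
#' @param input Path to an off-target CSV/TSV, or `NULL` to use `synthetic`.
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param scheme Feature scheme (see [node_features()]).
#' @param mode Cluster-sampling mode (see [cluster_sample()]).
#' @param independent_frac,test_frac Edge-split fractions.
#' @param negative_mode Negative-sampling restriction (see [split_edges()]).
#' @param gcn A [gcn_config()].
#' @param train A [train_config()].
#' @param walk A [walk_config()] for the optional baseline.
#' @param run_baseline Also run the random-walk baseline?
#' @param seed Master seed for sampling, splitting and training.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL,
                       synthetic = synthetic_config("benchmark", seed = 1),
                       scheme = "kmer-1", mode = "balanced",
                       independent_frac = 0.1, test_frac = 0.1,
                       negative_mode = "global",
                       gcn = gcn_config(), train = train_config(),
                       walk = walk_config(), run_baseline = FALSE,
                       seed = 1L) {
  scheme <- match.arg(scheme, FEATURE_SCHEMES)
  mode <- match.arg(mode, BALANCE_MODES)
  structure(list(input = input, synthetic = synthetic, scheme = scheme,
                 mode = mode, independent_frac = independent_frac,
                 test_frac = test_frac, negative_mode = negative_mode,
                 gcn = gcn, train = train, walk = walk,
                 run_baseline = isTRUE(run_baseline),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Execute a configured run and write its artifacts
#'
#' Orchestrates the whole pipeline — read or simulate, validate, cluster
#' sample, build graph, featurize, split, train, evaluate (and optionally the
#' walk baseline) — and writes to `outdir`: `config.json` (the exact
#' configuration used), `edges.tsv` + `nodes.tsv`, `features.tsv`,
#' `history.csv` (per-epoch loss/accuracy for train and validation),
#' `params.json` and `metrics.json`. Re-running from the stored config and
#' seed reproduces the metrics exactly.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @return The fitted `crispr_link_fit`, invisibly, with the baseline table
#'   (if requested) attached as attribute `"baseline"`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  records <- if (is.null(config$input)) {
    generate_dataset(config$synthetic)
  } else {
    read_offtarget_table(config$input)
  }
  records <- validate_records(records)

  fit <- run_link_experiment(
    records, config$scheme, config$mode, config$seed,
    independent_frac = config$independent_frac, test_frac = config$test_frac,
    negative_mode = config$negative_mode,
    gcn_cfg = config$gcn, cfg = config$train
  )

  baseline <- NULL
  if (config$run_baseline) {
    graph <- withr::with_seed(config$seed,
                              build_graph(cluster_sample(records, config$mode)))
    split <- withr::with_seed(config$seed + 1L,
                              split_edges(graph,
                                          independent_frac = config$independent_frac,
                                          test_frac = config$test_frac,
                                          negative_mode = config$negative_mode))
    wcfg <- config$walk
    wcfg$seed <- config$seed
    baseline <- walk_baseline(split, wcfg)
    attr(fit, "baseline") <- baseline
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_run_config(config, file.path(outdir, "config.json"))
    graph <- withr::with_seed(config$seed,
                              build_graph(cluster_sample(records, config$mode)))
    write_graph(graph, file.path(outdir, "edges.tsv"),
                file.path(outdir, "nodes.tsv"))
    write_features(node_features(graph, config$scheme),
                   file.path(outdir, "features.tsv"))
    readr::write_csv(fit$history, file.path(outdir, "history.csv"),
                     progress = FALSE)
    write_params(fit$params, file.path(outdir, "params.json"))
    metrics <- list(
      method = "gcn",
      seed = config$seed,
      scheme = config$scheme,
      mode = config$mode,
      auroc = setNames(as.list(fit$metrics$auroc), fit$metrics$tier),
      accuracy = setNames(as.list(fit$metrics$accuracy), fit$metrics$tier),
      loss_history = fit$history,
      config = run_config_list(config)
    )
    if (!is.null(baseline)) {
      metrics$baseline <- list(method = "walk_baseline",
                               auroc = setNames(as.list(baseline$auroc),
                                                baseline$operator))
    }
    write_metrics(metrics, file.path(outdir, "metrics.json"))
  }
  invisible(fit)
}

run_config_list <- function(config) {
  out <- unclass(config)
  out$synthetic <- if (!is.null(out$synthetic)) unclass(out$synthetic)
  out$gcn <- unclass(out$gcn)
  out$train <- unclass(out$train)
  out$walk <- unclass(out$walk)
  out
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `write_run_config()` returns `config` invisibly;
#'   `read_run_config()` the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(run_config_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(config)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- if (!is.null(raw$synthetic)) {
    s <- raw$synthetic
    synthetic_config(n_sgrna = s$n_sgrna, ot_per_cluster = s$ot_per_cluster,
                     not_per_cluster = s$not_per_cluster,
                     ot_mismatch_range = s$ot_mismatch_range,
                     not_mismatch_range = s$not_mismatch_range,
                     ot_mismatch_counts = s$ot_mismatch_counts,
                     not_mismatch_counts = s$not_mismatch_counts,
                     ot_base_weights = unlist(s$ot_base_weights),
                     perturb_pam = s$perturb_pam, seed = s$seed)
  }
  run_config(
    input = raw$input, synthetic = syn, scheme = raw$scheme, mode = raw$mode,
    independent_frac = raw$independent_frac, test_frac = raw$test_frac,
    negative_mode = raw$negative_mode,
    gcn = gcn_config(raw$gcn$n_layers, raw$gcn$units, raw$gcn$dropout_rate,
                     raw$gcn$bias),
    train = train_config(raw$train$learning_rate, raw$train$epochs,
                         raw$train$operator, raw$train$threshold,
                         raw$train$shuffle_labels, raw$train$seed),
    walk = walk_config(raw$walk$walk_length, raw$walk$walks_per_node,
                       raw$walk$p, raw$walk$q, raw$walk$embedding_dim,
                       raw$walk$window, raw$walk$epochs, raw$walk$negative,
                       raw$walk$learning_rate, raw$walk$seed),
    run_baseline = raw$run_baseline, seed = raw$seed
  )
}
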