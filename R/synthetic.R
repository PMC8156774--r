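#' Generate random sgRNA sequences
#'
#' Draws 20-nt spacers uniformly over A/C/G/T and appends an NGG PAM (first
#' PAM base uniform), the canonical SpCas9 motif. Collisions are resampled so
#' all sequences are distinct.
#'
#' @param n Number of sgRNAs (>= 1).
#' @param seed Integer seed; the same seed reproduces the same sequences.
#' @return Character vector of `n` distinct 23-nt sequences ending in "GG".
#' @examples
#' generate_sgrna(3, seed = 1)
#' @export
generate_sgrna <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  draw <- function() {
    out <- character(0)
    while (length(out) < n) {
      spacer <- vapply(seq_len(n - length(out)), function(i) {
        paste0(sample(DNA_BASES, SPACER_LEN, replace = TRUE), collapse = "")
      }, character(1))
      pam <- paste0(sample(DNA_BASES, length(spacer), replace = TRUE), "GG")
      out <- unique(c(out, paste0(spacer, pam)))
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Mutate a target site away from its sgRNA
#'
#' Substitutes exactly `n_mismatch` spacer positions (1-20) to a different
#' base; the PAM (21-23) is untouched unless `perturb_pam`, which may change
#' the first PAM base only (keeping -GG). `base_weights` biases the choice of
#' replacement base (renormalized after excluding the original base), which is
#' how the synthetic generator plants a compositional OT signal.
#'
#' @param sgrna A 23-nt sequence.
#' @param n_mismatch Number of spacer substitutions, 0-6.
#' @param perturb_pam If `TRUE`, the first PAM base may also be resampled.
#' @param base_weights Optional numeric vector of length 4 (A, C, G, T
#'   sampling weights for replacement bases).
#' @param seed Optional integer seed.
#' @return A 23-nt sequence at spacer Hamming distance `n_mismatch` from
#'   `sgrna`.
#' @export
mutate_target <- function(sgrna, n_mismatch, perturb_pam = FALSE,
                          base_weights = NULL, seed = NULL) {
  if (n_mismatch < 0 || n_mismatch > 6) {
    abort("n_mismatch must be between 0 and 6")
  }
  run <- function() mutate_target_impl(sgrna, n_mismatch, perturb_pam, base_weights)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

mutate_target_impl <- function(sgrna, n_mismatch, perturb_pam, base_weights) {
  chars <- strsplit(sgrna, "", fixed = TRUE)[[1]]
  if (n_mismatch > 0) {
    pos <- sample.int(SPACER_LEN, n_mismatch)
    for (p in pos) {
      chars[p] <- sample_base_excluding(chars[p], base_weights)
    }
  }
  if (perturb_pam) {
    chars[21] <- sample(DNA_BASES, 1)
  }
  paste0(chars, collapse = "")
}

sample_base_excluding <- function(base, base_weights = NULL) {
  others <- setdiff(DNA_BASES, base)
  if (is.null(base_weights)) {
    return(sample(others, 1))
  }
  w <- base_weights[match(others, DNA_BASES)]
  sample(others, 1, prob = w / sum(w))
}

#' Configure the synthetic off-target generator
#'
#' Describes a synthetic dataset with the cluster structure of curated
#' sequence-only off-target benchmarks: per-sgRNA clusters of 23-nt candidate
#' sites within at most six spacer mismatches of the guide, labelled 1 (OT,
#' confirmed off-target) or 0 (NOT, no observed cleavage). The OT-vs-NOT
#' signal is planted two ways: OT sites draw fewer mismatches than NOT sites
#' (ranges may overlap, which tunes difficulty), and OT substitutions are
#' biased toward G/C while NOT substitutions are uniform.
#'
#' The `"benchmark"` preset mirrors the shape of the curated 29-guide
#' HEK293T/K562 benchmark used by sequence-only deep-learning predictors: 29
#' clusters totalling 626 OT records (distributed as evenly as possible), and
#' twice as many NOT records available in every cluster.
#'
#' @param preset `"custom"` or `"benchmark"`.
#' @param n_sgrna Number of sgRNA clusters.
#' @param ot_per_cluster Integer vector (recycled) of OT records per cluster,
#'   or a single total when `ot_total` is used via the preset.
#' @param not_per_cluster Integer vector (recycled) of NOT records per cluster.
#' @param ot_mismatch_range,not_mismatch_range Integer ranges within 0-6 from
#'   which per-record spacer mismatch counts are drawn uniformly.
#' @param ot_mismatch_counts,not_mismatch_counts Optional named integer vectors
#'   (names = mismatch count) fixing the exact per-cluster histogram instead of
#'   sampling; overrides the range and per-cluster counts.
#' @param ot_base_weights Replacement-base weights for OT substitutions
#'   (A, C, G, T); the default favours G/C. NOT substitutions are uniform.
#' @param perturb_pam Should NOT sites also perturb the first PAM base?
#' @param seed Integer seed making the dataset fully reproducible.
#' @return A `synthetic_config` list.
#' @examples
#' cfg <- synthetic_config("benchmark", seed = 1)
#' sum(cfg$ot_per_cluster)  # 626
#' @export
synthetic_config <- function(preset = c("custom", "benchmark"),
                             n_sgrna = 10,
                             ot_per_cluster = 10,
                             not_per_cluster = 20,
                             ot_mismatch_range = 1:3,
                             not_mismatch_range = 3:6,
                             ot_mismatch_counts = NULL,
                             not_mismatch_counts = NULL,
                             ot_base_weights = c(A = 0.15, C = 0.35,
                                                 G = 0.35, T = 0.15),
                             perturb_pam = FALSE,
                             seed = NULL) {
  preset <- match.arg(preset)
  if (preset == "benchmark") {
    n_sgrna <- 29L
    ot_per_cluster <- distribute_counts(626L, 29L)
    not_per_cluster <- 2L * ot_per_cluster
  }
  stopifnot(
    all(ot_mismatch_range >= 0 & ot_mismatch_range <= 6),
    all(not_mismatch_range >= 0 & not_mismatch_range <= 6),
    n_sgrna >= 0, all(ot_per_cluster >= 0), all(not_per_cluster >= 0)
  )
  structure(list(
    n_sgrna = as.integer(n_sgrna),
    ot_per_cluster = rep_len(as.integer(ot_per_cluster), max(n_sgrna, 1L)),
    not_per_cluster = rep_len(as.integer(not_per_cluster), max(n_sgrna, 1L)),
    ot_mismatch_range = as.integer(ot_mismatch_range),
    not_mismatch_range = as.integer(not_mismatch_range),
    ot_mismatch_counts = ot_mismatch_counts,
    not_mismatch_counts = not_mismatch_counts,
    ot_base_weights = ot_base_weights,
    perturb_pam = isTRUE(perturb_pam),
    seed = seed
  ), class = "synthetic_config")
}

# Split `total` into `n` near-equal integer parts (first parts get the
# remainder), so sum(distribute_counts(626, 29)) == 626 deterministically.
distribute_counts <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  as.integer(base + (seq_len(n) <= extra))
}

#' Generate a synthetic off-target table
#'
#' Materializes the dataset described by a [synthetic_config()]: for each
#' generated sgRNA, OT records (label 1) and NOT records (label 0) produced by
#' [mutate_target()] with the configured mismatch counts. Within a cluster a
#' NOT target is resampled if it collides with an OT target or with any sgRNA
#' (so node roles stay unambiguous); target collisions across clusters are
#' allowed, as shared genomic sites are real. Output always passes
#' [validate_records()].
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `sgrna`, `target`, `label`, byte-identical
#'   across runs with equal seeds.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  run <- function() generate_dataset_impl(config)
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

generate_dataset_impl <- function(config) {
  if (config$n_sgrna == 0L) {
    return(tibble(sgrna = character(), target = character(), label = integer()))
  }
  guides <- generate_sgrna(config$n_sgrna)
  clusters <- map(seq_len(config$n_sgrna), function(i) {
    g <- guides[i]
    n_ot <- config$ot_per_cluster[i]
    n_not <- config$not_per_cluster[i]
    mm_ot <- mismatch_draw(n_ot, config$ot_mismatch_range,
                           config$ot_mismatch_counts)
    mm_not <- mismatch_draw(n_not, config$not_mismatch_range,
                            config$not_mismatch_counts)
    ot <- vapply(mm_ot, function(m) {
      mutate_target_impl(g, m, perturb_pam = FALSE,
                         base_weights = config$ot_base_weights)
    }, character(1))
    forbidden <- c(guides, ot)
    nt <- vapply(mm_not, function(m) {
      for (try in 1:50) {
        cand <- mutate_target_impl(g, m, perturb_pam = config$perturb_pam,
                                   base_weights = NULL)
        if (!cand %in% forbidden) return(cand)
      }
      abort("could not generate a NOT target distinct from OT/sgRNA sequences")
    }, character(1))
    tibble(
      sgrna = g,
      target = c(ot, nt),
      label = rep(c(1L, 0L), c(length(ot), length(nt)))
    )
  })
  bind_rows(clusters)
}

mismatch_draw <- function(n, range, counts) {
  if (n == 0L) return(integer(0))
  if (!is.null(counts)) {
    mm <- rep(as.integer(names(counts)), counts)
    if (length(mm) != n) {
      abort("fixed mismatch counts must sum to the per-cluster record count")
    }
    return(mm)
  }
  if (length(range) == 1L) rep(range, n) else sample(range, n, replace = TRUE)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_sgrna, " sgRNA clusters; ",
      sum(x$ot_per_cluster), " OT / ", sum(x$not_per_cluster),
      " NOT records; OT mismatches {",
      paste(range(x$ot_mismatch_range), collapse = "-"), "}, NOT {",
      paste(range(x$not_mismatch_range), collapse = "-"), "}\n", sep = "")
  invisible(x)
}
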