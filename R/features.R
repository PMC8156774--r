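# Resolve the sequence list (node-ID order) from an ot_graph or a plain
# character vector; returns list(sequences, node_id).
resolve_sequences <- function(x) {
  if (inherits(x, "ot_graph")) {
    list(sequences = x$nodes$sequence, node_id = x$nodes$node_id)
  } else if (is.character(x)) {
    list(sequences = x, node_id = seq_along(x) - 1L)
  } else {
    abort("expected an ot_graph or a character vector of sequences")
  }
}

#' k-mer occurrence features
#'
#' Counts overlapping (stride-1) occurrences of every length-`k` DNA word in
#' each 23-nt sequence. Columns are the `4^k` k-mers in lexicographic order
#' (AA..A first), so the feature dimension is 4, 16 or 64 for k = 1, 2, 3 and
#' every row sums to `23 - k + 1`. Counting is delegated to
#' [Biostrings::oligonucleotideFrequency()].
#'
#' @param x An [ot_graph][build_graph()] (features for all nodes in node-ID
#'   order) or a character vector of 23-nt sequences.
#' @param k Word length, one of 1, 2, 3.
#' @return A feature tibble: `node_id` column then one count column per k-mer;
#'   `attr(, "scheme")` is `"kmer-<k>"`.
#' @examples
#' kmer_features(c(strrep("A", 23)), k = 1)
#' @export
kmer_features <- function(x, k = 1) {
  if (!k %in% 1:3) abort("k must be 1, 2 or 3")
  s <- resolve_sequences(x)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(s$sequences), width = k
  )
  out <- as_tibble(counts)
  out <- dplyr::bind_cols(tibble(node_id = s$node_id), out)
  attr(out, "scheme") <- paste0("kmer-", k)
  out
}

#' Positional one-hot features
#'
#' Encodes which of the 4 nucleotides occupies each of the 23 positions,
#' giving 92 binary features per sequence. Columns are position-major
#' (`pos01_A, pos01_C, pos01_G, pos01_T, pos02_A, ...`); each row has exactly
#' 23 ones, and distinct sequences always receive distinct rows.
#'
#' @inheritParams kmer_features
#' @return A feature tibble: `node_id` then 92 binary columns;
#'   `attr(, "scheme")` is `"positional"`.
#' @export
positional_features <- function(x) {
  s <- resolve_sequences(x)
  chars <- matrix(unlist(strsplit(s$sequences, "", fixed = TRUE), use.names = FALSE),
                  ncol = SEQ_LEN, byrow = TRUE)
  mats <- lapply(seq_len(SEQ_LEN), function(p) {
    m <- matrix(0L, nrow = nrow(chars), ncol = 4L)
    m[cbind(seq_len(nrow(chars)), match(chars[, p], DNA_BASES))] <- 1L
    m
  })
  values <- do.call(cbind, mats)
  colnames(values) <- as.vector(t(outer(
    sprintf("pos%02d", seq_len(SEQ_LEN)), DNA_BASES, paste, sep = "_"
  )))
  out <- dplyr::bind_cols(tibble(node_id = s$node_id), as_tibble(values))
  attr(out, "scheme") <- "positional"
  out
}

#' Compute node features by scheme name
#'
#' @inheritParams kmer_features
#' @param scheme One of `"kmer-1"`, `"kmer-2"`, `"kmer-3"`, `"positional"`.
#' @param row_normalize Divide each feature row by its sum? Off by default:
#'   feature scale is handled by the propagation operator's degree
#'   normalization.
#' @return A feature tibble as from [kmer_features()] / [positional_features()].
#' @export
node_features <- function(x, scheme = c("kmer-1", "kmer-2", "kmer-3",
                                        "positional"),
                          row_normalize = FALSE) {
  scheme <- match.arg(scheme)
  out <- switch(scheme,
    "kmer-1" = kmer_features(x, 1),
    "kmer-2" = kmer_features(x, 2),
    "kmer-3" = kmer_features(x, 3),
    positional = positional_features(x)
  )
  if (row_normalize) {
    m <- feature_matrix(out)
    m <- m / rowSums(m)
    out[, -1] <- as_tibble(m)
  }
  out
}

#' Extract the numeric matrix from a feature tibble
#'
#' @param features A feature tibble (first column `node_id`).
#' @return A numeric N x F matrix in node-ID order, feature names as colnames.
#' @export
feature_matrix <- function(features) {
  stopifnot(names(features)[1] == "node_id")
  m <- as.matrix(features[order(features$node_id), -1, drop = FALSE])
  storage.mode(m) <- "double"
  m
}
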