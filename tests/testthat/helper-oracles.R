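# Independent oracles and tiny fixtures shared across test files.

# Brute-force auROC: enumerate all positive-negative pairs, ties count half.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Naive sliding-window k-mer count of one sequence against a k-mer vocabulary.
kmer_count_bruteforce <- function(seq, k) {
  kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE)[, k:1, drop = FALSE],
                      1, paste, collapse = ""))
  windows <- substring(seq, 1:(nchar(seq) - k + 1), k:nchar(seq))
  vapply(kmers, function(w) sum(windows == w), integer(1))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

spacer <- function(x) substr(x, 1, 20)
pam <- function(x) substr(x, 21, 23)

# A 3-guide, well-formed record tibble with deterministic content.
toy_records <- function() {
  generate_dataset(synthetic_config(
    n_sgrna = 3, ot_per_cluster = 4, not_per_cluster = 6,
    ot_mismatch_range = 1:2, not_mismatch_range = 4:6, seed = 101
  ))
}

# A random small graph (n nodes, some edges) plus feature matrix, for
# operator-level checks that do not need biological structure.
random_graph_fixture <- function(n_nodes, n_edges, f0 = 4) {
  pairs <- t(combn(n_nodes, 2)) - 1L
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- tibble::tibble(from = pairs[pick, 1], to = pairs[pick, 2])
  edges <- edges[order(edges$from, edges$to), ]
  nodes <- tibble::tibble(node_id = 0:(n_nodes - 1),
                          sequence = paste0("n", 0:(n_nodes - 1)),
                          role = "OT")
  g <- crisprlink:::new_ot_graph(nodes, edges)
  X <- matrix(runif(n_nodes * f0), n_nodes, f0)
  list(graph = g, X = X)
}

# Dense reference of the normalized propagation operator.
dense_propagation <- function(graph) {
  n <- nrow(graph$nodes)
  A <- matrix(0, n, n)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$from[i] + 1
    b <- graph$edges$to[i] + 1
    A[a, b] <- 1
    A[b, a] <- 1
  }
  A_hat <- A + diag(n)
  d <- rowSums(A_hat)
  diag(1 / sqrt(d)) %*% A_hat %*% diag(1 / sqrt(d))
}
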