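# Flatten / restore a link-model parameter list, and a central
# finite-difference gradient of the training loss, for gradient checks.

flatten_params <- function(p) c(unlist(p$gcn), p$head$w, p$head$b)

unflatten_params <- function(v, tmpl) {
  i <- 0L
  gcn <- lapply(tmpl$gcn, function(W) {
    out <- matrix(v[i + seq_along(W)], nrow(W))
    i <<- i + length(W)
    out
  })
  w <- v[i + seq_along(tmpl$head$w)]
  i <- i + length(tmpl$head$w)
  list(gcn = gcn, head = list(w = w, b = v[i + 1L]))
}

numeric_link_grad <- function(params, X, S, pairs, labels, gcn_cfg, operator,
                              eps = 1e-6) {
  v0 <- flatten_params(params)
  vapply(seq_along(v0), function(j) {
    vp <- v0; vp[j] <- vp[j] + eps
    vm <- v0; vm[j] <- vm[j] - eps
    lp <- crisprlink:::link_loss(unflatten_params(vp, params), X, S, pairs,
                                 labels, gcn_cfg, operator)
    lm <- crisprlink:::link_loss(unflatten_params(vm, params), X, S, pairs,
                                 labels, gcn_cfg, operator)
    (lp - lm) / (2 * eps)
  }, numeric(1))
}

# 5-node fixture used by the gradient checks: sgRNA hub with two OT edges,
# two isolated NOT nodes.
five_node_fixture <- function(f0 = 4, seed = 42) {
  withr::with_seed(seed, {
    nodes <- tibble::tibble(node_id = 0:4, sequence = paste0("s", 0:4),
                            role = c("SGRNA", "OT", "OT", "NOT", "NOT"))
    edges <- tibble::tibble(from = c(0L, 0L), to = c(1L, 2L))
    g <- crisprlink:::new_ot_graph(nodes, edges)
    list(graph = g, S = compute_adjacency(g)$S,
         X = matrix(runif(5 * f0), 5, f0),
         pairs = tibble::tibble(from = c(0L, 0L, 1L, 3L),
                                to = c(1L, 2L, 3L, 4L)),
         labels = c(1, 1, 0, 0))
  })
}
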