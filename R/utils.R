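# Internal graph helpers shared by the dynamics, centrality and
# total-support code.

# igraph view of the signal flow: directed edges keep their orientation,
# undirected edges become reciprocal arc pairs. Used for hop distances,
# reachability and betweenness; no weight attribute on purpose (the
# structural measures are hop-count based).
flow_graph <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  e <- net$edges
  if (nrow(e)) {
    from <- c(e$source, e$target[!e$directed])
    to <- c(e$target, e$source[!e$directed])
    d <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  } else {
    d <- data.frame(from = character(), to = character(),
                    stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(d, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

# Reachability closure of the influence flow, from an influence matrix:
# reach[v, u] is TRUE when u lies downstream of v (v influences ...
# influences u); diagonal TRUE. Drives the anchoring computation in the
# total-support inner loop.
reach_closure <- function(mat) {
  stopifnot(inherits(mat, "influence_matrix"))
  n <- length(mat$nodes)
  adj <- t(mat$S) > 0  # adj[v, u]: v directly influences u
  reach <- adj
  diag(reach) <- TRUE
  # repeated squaring of the boolean adjacency; n is small (<= a few
  # hundred) so dense logical products are fine
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  dimnames(reach) <- list(mat$nodes, mat$nodes)
  reach
}
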