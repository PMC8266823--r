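#' Shortest hop distances from one node
#'
#' Unweighted shortest-path distances under the hybrid traversal
#' semantics of heterogeneous signaling networks: directed edges are
#' traversed source-to-target only, undirected edges both ways.
#' Unreachable nodes get `Inf`. Edge weights play no role here; the
#' structural measures are hop-count based.
#'
#' @param net a [signaling_network()].
#' @param u source node id.
#' @return named numeric vector of distances to every node (0 for `u`).
#' @export
shortest_distances <- function(net, u) {
  u <- as.character(u)
  if (!u %in% net$nodes) stop("unknown node '", u, "'", call. = FALSE)
  d <- distance_matrix(net)[u, ]
  d
}

# Full hop-distance matrix (rows = sources), via the flow digraph.
distance_matrix <- function(net) {
  g <- flow_graph(net)
  d <- igraph::distances(g, mode = "out")
  d[net$nodes, net$nodes, drop = FALSE]
}

#' Classic closeness centrality
#'
#' `C_clo(u) = 1 / sum_v d(u, v)`: the reciprocal of the total shortest
#' distance to all other nodes. On networks where some node is
#' unreachable from `u` the sum is infinite and the measure degenerates;
#' it is then reported as `NA` (undefined) rather than 0, which is the
#' very defect the averaged-reciprocal variant repairs.
#'
#' @inheritParams shortest_distances
#' @return a scalar, or `NA` when some node is unreachable from `u`.
#' @seealso [closeness_variant()]
#' @export
closeness_classic <- function(net, u) {
  if (length(net$nodes) < 2L) stop("needs at least 2 nodes", call. = FALSE)
  d <- shortest_distances(net, u)
  d <- d[names(d) != u]
  if (any(!is.finite(d))) return(NA_real_)
  1 / sum(d)
}

#' Averaged-reciprocal closeness (directed-network variant)
#'
#' \deqn{C_{clo\text{-}v}(u) = \frac{1}{|V|-1} \sum_{v \ne u} \frac{1}{d(u,v)}}
#'
#' Unreachable nodes contribute 0 (`1/Inf`), so the measure stays
#' well-defined on directed or disconnected networks. Values lie in
#' `[0, 1]`, with 1 attained exactly when `u` reaches every other node
#' at distance 1 (e.g. on a complete graph or an out-star hub).
#'
#' @inheritParams shortest_distances
#' @return a scalar in `[0, 1]`.
#' @export
closeness_variant <- function(net, u) {
  if (length(net$nodes) < 2L) {
    stop("closeness variant undefined for a single-node network",
         call. = FALSE)
  }
  d <- shortest_distances(net, u)
  d <- d[names(d) != u]
  mean(1 / d)
}

#' Reachability count
#'
#' The number of nodes reachable from `u` by a path under the hybrid
#' traversal semantics, excluding `u` itself; an integer in
#' `[0, |V| - 1]`.
#'
#' @inheritParams shortest_distances
#' @return an integer count.
#' @export
reachability <- function(net, u) {
  d <- shortest_distances(net, u)
  sum(is.finite(d[names(d) != u]))
}

#' Hierarchical closeness
#'
#' `C_hc(u) = N_R(u) + C_clo-v(u)`: reachability plus the
#' averaged-reciprocal closeness. Because the closeness term is at most
#' 1, the ordering is lexicographic -- downstream coverage first,
#' closeness as tiebreak -- which is what makes the measure rank
#' upstream regulators highly on directed signaling networks.
#'
#' @inheritParams shortest_distances
#' @return a scalar in `[0, N-1+1]`.
#' @export
hierarchical_closeness <- function(net, u) {
  reachability(net, u) + closeness_variant(net, u)
}

#' Per-node centrality table
#'
#' Computes, for every node: classic closeness (`NA` where undefined),
#' the averaged-reciprocal closeness variant, reachability, hierarchical
#' closeness, degree (number of incident edges, directed and undirected
#' alike), and shortest-path betweenness under the same hybrid traversal
#' semantics as the distances.
#'
#' @param net a [signaling_network()].
#' @return a data frame with columns `node`, `closeness_classic`,
#'   `closeness`, `reachability`, `hierarchical_closeness`, `degree`,
#'   `betweenness`, one row per node in declaration order.
#' @export
centrality_table <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  nodes <- net$nodes
  n <- length(nodes)
  if (n < 2L) stop("centrality table needs at least 2 nodes", call. = FALSE)
  d <- distance_matrix(net)
  diag(d) <- NA  # exclude self-terms below
  inv <- 1 / d
  clo_v <- rowSums(inv, na.rm = TRUE) / (n - 1)
  reach <- rowSums(is.finite(d), na.rm = TRUE)
  tot <- rowSums(d, na.rm = TRUE)
  clo_c <- ifelse(is.finite(tot), 1 / tot, NA_real_)
  deg <- vapply(nodes, function(u) {
    sum(net$edges$source == u | net$edges$target == u)
  }, numeric(1))
  btw <- igraph::betweenness(flow_graph(net), directed = TRUE)[nodes]
  data.frame(node = nodes,
             closeness_classic = unname(clo_c),
             closeness = unname(clo_v),
             reachability = unname(as.integer(reach)),
             hierarchical_closeness = unname(reach + clo_v),
             degree = unname(as.integer(deg)),
             betweenness = unname(btw),
             stringsAsFactors = FALSE)
}
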