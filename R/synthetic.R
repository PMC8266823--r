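#' Generate a random directed scale-free network
#'
#' Barabasi-Albert preferential attachment with a directedness
#' convention: growth starts from `m` isolated seed nodes, the first
#' newcomer attaches to all of them, and every later newcomer attaches
#' to `m` distinct existing nodes chosen with probability proportional
#' to total degree. Each attachment edge is then oriented uniformly at
#' random (the `"uniform"` rule), giving a directed network with
#' `(n - m) * m` edges, a few hubs and many low-degree nodes -- the
#' degree structure of real signaling networks. The same seed always
#' reproduces the same network.
#'
#' @param n node count (>= 2); 50 in the validation ensemble.
#' @param m edges added per newcomer, 1 or 2 in the validation ensemble
#'   (`1 <= m < n`).
#' @param seed integer RNG seed.
#' @param orientation edge-orientation rule; only `"uniform"` is
#'   implemented.
#' @return a [signaling_network()] with nodes `v01, v02, ...` and all
#'   edges directed with weight 1.
#' @export
generate_ba_directed <- function(n, m, seed, orientation = "uniform") {
  if (!is.numeric(n) || n < 2 || !is.numeric(m) || m < 1 || m >= n) {
    stop("need n >= 2 and 1 <= m < n", call. = FALSE)
  }
  orientation <- match.arg(orientation, "uniform")
  n <- as.integer(n)
  m <- as.integer(m)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  deg <- integer(n)
  n_edges <- (n - m) * m
  from <- to <- integer(n_edges)
  k <- 0L
  for (new in (m + 1L):n) {
    existing <- seq_len(new - 1L)
    targets <- if (new == m + 1L) {
      existing  # first newcomer links to every seed node
    } else {
      sample(existing, m, prob = deg[existing])
    }
    for (tv in targets) {
      k <- k + 1L
      if (stats::runif(1) < 0.5) {
        from[k] <- new; to[k] <- tv
      } else {
        from[k] <- tv; to[k] <- new
      }
      deg[new] <- deg[new] + 1L
      deg[tv] <- deg[tv] + 1L
    }
  }
  ids <- sprintf("v%02d", seq_len(n))
  signaling_network(
    ids,
    data.frame(source = ids[from], target = ids[to], directed = TRUE,
               weight = 1, subtype = "", stringsAsFactors = FALSE),
    name = sprintf("ba_n%d_m%d_seed%d", n, m, seed))
}

#' Deterministic 12-gene demonstration network
#'
#' A fixed disease-network fixture at the scale of the weighted-versus-
#' unweighted competition demonstration: 12 genes, 19 mixed
#' directed/undirected interactions, with gene `g01` wired as the
#' natural driver. The `"unweighted"` variant keeps every weight at 1;
#' the `"weighted"` variant changes only a handful of weights (same
#' topology), which is enough to flip the steady-state sign of several
#' genes when `g01` competes against the outside opponent -- the
#' large-fluctuation effect of adjacency weights on competition
#' outcomes. The wiring is a synthetic emulation of that scale, not a
#' reconstruction of any published figure's exact adjacency.
#'
#' @param variant `"unweighted"` (all weights 1) or `"weighted"`.
#' @return a [signaling_network()] with 12 nodes and 19 edges.
#' @export
make_demo_network <- function(variant = c("unweighted", "weighted")) {
  variant <- match.arg(variant)
  edges <- data.frame(
    source   = c("g01", "g01", "g01", "g02", "g03", "g04", "g05", "g06",
                 "g07", "g08", "g02", "g05", "g09", "g10", "g04", "g03",
                 "g11", "g12", "g06"),
    target   = c("g02", "g03", "g04", "g05", "g05", "g06", "g07", "g07",
                 "g08", "g09", "g03", "g06", "g10", "g11", "g09", "g08",
                 "g12", "g10", "g12"),
    directed = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                 TRUE, TRUE, TRUE),
    weight   = 1,
    subtype  = "",
    stringsAsFactors = FALSE)
  if (variant == "weighted") {
    # weaken the driver's outgoing influence and one mid-path relay;
    # topology untouched
    w <- rep(1, nrow(edges))
    w[edges$source == "g01"] <- 0.1
    w[edges$source == "g05" & edges$target == "g07"] <- 0.2
    w[edges$source == "g08" & edges$target == "g09"] <- 0.2
    edges$weight <- w
  }
  signaling_network(sprintf("g%02d", 1:12), edges,
                    name = paste0("demo12_", variant))
}

#' Small fixed networks where closeness and degree/betweenness disagree
#'
#' Deterministic fixtures (frozen seeds of the scale-free generator) on
#' which the node with the highest hierarchical closeness is a different
#' node from the one with the highest degree (`contrast = "degree"`) or
#' the highest betweenness (`contrast = "betweenness"`), and the
#' closeness champion attains the strictly higher total support. They
#' demonstrate that downstream coverage, not raw connectivity, predicts
#' who wins the outside competition.
#'
#' @param contrast which structural baseline the fixture separates from
#'   hierarchical closeness.
#' @return a [signaling_network()].
#' @seealso [compare_centralities()]
#' @export
make_centrality_contrast_network <- function(contrast = c("degree",
                                                          "betweenness")) {
  contrast <- match.arg(contrast)
  seed <- switch(contrast, degree = 2L, betweenness = 3L)
  net <- generate_ba_directed(12, 2, seed)
  net$name <- paste0("contrast_", contrast)
  net
}
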