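# Shared fixtures and an independent brute-force oracle for the
# competition dynamics. The oracle builds its receiver matrix directly
# from the edge list and iterates the consensus update; it shares no
# code with the package's influence-matrix or closed-form solver paths.

# small random heterogeneous network; may legitimately contain isolated
# nodes or be edgeless at low p
random_network <- function(n, seed, p = 0.35, undirected_frac = 0.3,
                           weighted = FALSE) {
  set.seed(seed)
  nodes <- sprintf("r%02d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  pairs <- pairs[, keep, drop = FALSE]
  if (ncol(pairs) == 0L) return(signaling_network(nodes))
  undir <- stats::runif(ncol(pairs)) < undirected_frac
  flip <- stats::runif(ncol(pairs)) < 0.5
  src <- ifelse(flip, pairs[2L, ], pairs[1L, ])
  tgt <- ifelse(flip, pairs[1L, ], pairs[2L, ])
  w <- if (weighted) round(stats::runif(ncol(pairs), 0.2, 1), 3) else 1
  signaling_network(nodes, data.frame(
    source = nodes[src], target = nodes[tgt], directed = !undir,
    weight = w, stringsAsFactors = FALSE))
}

# brute-force steady state by direct iteration of the consensus update on
# a hand-built augmented receiver matrix; returns the normal-node states
oracle_steady <- function(net, leader, gamma, beta_weight = 1,
                          tol = 1e-13, max_iter = 5e5) {
  ids <- c(net$nodes, "..beta")
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- net$edges
  for (k in seq_len(nrow(e))) {
    S[e$target[k], e$source[k]] <- S[e$target[k], e$source[k]] + e$weight[k]
    if (!e$directed[k]) {
      S[e$source[k], e$target[k]] <- S[e$source[k], e$target[k]] + e$weight[k]
    }
  }
  S[gamma, "..beta"] <- beta_weight
  S["..beta", gamma] <- beta_weight
  D <- rowSums(S)
  eps <- 0.5 / max(D)
  x <- stats::setNames(numeric(n), ids)
  x[leader] <- 1
  x["..beta"] <- -1
  for (i in seq_len(max_iter)) {
    xn <- x + eps * (as.vector(S %*% x) - D * x)
    xn[leader] <- 1
    xn["..beta"] <- -1
    done <- max(abs(xn - x)) < tol
    x <- xn
    if (done) break
  }
  x[setdiff(net$nodes, leader)]
}

# brute-force total support: one oracle run per attachment point
oracle_tos <- function(net, leader, beta_weight = 1) {
  gammas <- setdiff(net$nodes, leader)
  sum(vapply(gammas, function(g) {
    oracle_steady(net, leader, g, beta_weight)[[g]]
  }, numeric(1)))
}

path_net <- function() {
  signaling_network(c("a", "b", "c"), data.frame(
    source = c("a", "b"), target = c("b", "c"), directed = TRUE))
}

out_star <- function(n_leaves = 3) {
  leaves <- sprintf("l%d", seq_len(n_leaves))
  signaling_network(c("hub", leaves), data.frame(
    source = "hub", target = leaves, directed = TRUE))
}

# W_max of the beta-augmented system, recounted from first principles
augmented_wmax <- function(mat, gamma, beta_weight = 1) {
  D <- mat$D
  D[gamma] <- D[gamma] + beta_weight
  max(D, beta_weight)
}
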