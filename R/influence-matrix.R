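#' Build the influence matrix of a signaling network
#'
#' The dynamics run on a receiver-oriented weight matrix `S`: entry
#' `S[u, v]` is the weight with which node `v` influences node `u`. A
#' directed edge `a -> b` (KEGG arrow orientation, `a` acts on `b`)
#' contributes `S[b, a] = w`; an undirected edge `a -- b` contributes both
#' `S[a, b] = w` and `S[b, a] = w`. When a directed and an undirected edge
#' join the same pair, their weights add. The diagonal is zero.
#'
#' Row sums `D[u] = sum_v S[u, v]` are each node's total received
#' influence weight, and `W_max = max_u D[u]` bounds the admissible step
#' size of the consensus update (`0 < epsilon < 1/W_max`).
#'
#' @param net a [signaling_network()].
#' @return an object of class `influence_matrix`: a list with the dense
#'   matrix `S` (rows/columns in node declaration order), the row-sum
#'   vector `D`, the scalar `W_max`, and the node vector `nodes`.
#' @seealso [epsilon_bound()], [solve_steady_state()]
#' @export
to_influence_matrix <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  nodes <- net$nodes
  n <- length(nodes)
  S <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- net$edges
  if (nrow(e)) {
    si <- match(e$source, nodes)
    ti <- match(e$target, nodes)
    for (k in seq_len(nrow(e))) {
      if (e$directed[k]) {
        S[ti[k], si[k]] <- S[ti[k], si[k]] + e$weight[k]
      } else {
        S[si[k], ti[k]] <- S[si[k], ti[k]] + e$weight[k]
        S[ti[k], si[k]] <- S[ti[k], si[k]] + e$weight[k]
      }
    }
  }
  new_influence_matrix(S, nodes)
}

new_influence_matrix <- function(S, nodes) {
  D <- rowSums(S)
  structure(list(S = S, D = D, W_max = if (length(D)) max(D) else 0,
                 nodes = nodes),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("influence_matrix: %d nodes, %d nonzero entries, W_max = %g\n",
              length(x$nodes), sum(x$S > 0), x$W_max))
  invisible(x)
}

# Reserved identifier for the virtual outside competitor.
BETA_ID <- ".beta"

# Augment an influence matrix with the virtual competitor beta attached to
# `gamma` by an undirected link of weight `beta_weight`. Beta's own row is
# kept (its state is pinned, so the row never matters dynamically, but the
# partitioned-system algebra uses it).
augment_with_beta <- function(mat, gamma, beta_weight = 1) {
  stopifnot(inherits(mat, "influence_matrix"))
  if (BETA_ID %in% mat$nodes) {
    stop("node id '", BETA_ID, "' is reserved for the outside competitor",
         call. = FALSE)
  }
  gi <- match(gamma, mat$nodes)
  if (is.na(gi)) stop("unknown perturbed node '", gamma, "'", call. = FALSE)
  if (!is.numeric(beta_weight) || beta_weight <= 0 || beta_weight > 1) {
    stop("beta_weight must lie in (0, 1]", call. = FALSE)
  }
  n <- length(mat$nodes)
  nodes <- c(mat$nodes, BETA_ID)
  S <- matrix(0, n + 1L, n + 1L, dimnames = list(nodes, nodes))
  S[seq_len(n), seq_len(n)] <- mat$S
  S[gi, n + 1L] <- beta_weight
  S[n + 1L, gi] <- beta_weight
  new_influence_matrix(S, nodes)
}

#' Upper bound on the consensus step size
#'
#' The synchronous consensus update is stable for step sizes
#' `0 < epsilon < 1/W_max`, where `W_max` is the largest total received
#' influence weight over all nodes (including the competitor link when the
#' matrix has been augmented). For an edgeless network `W_max = 0` and the
#' bound is `+Inf`; the update is then a no-op for any epsilon.
#'
#' @param mat an [to_influence_matrix()] result, possibly
#'   beta-augmented.
#' @return `1 / W_max`, or `Inf` when `W_max = 0`.
#' @export
epsilon_bound <- function(mat) {
  stopifnot(inherits(mat, "influence_matrix"))
  if (mat$W_max == 0) Inf else 1 / mat$W_max
}
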