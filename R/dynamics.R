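#' Configure a leader-versus-outside-competitor run
#'
#' Sets up one configuration of the outside competition: the leader
#' `alpha` (an in-network node whose state is pinned at +1), the virtual
#' opponent beta (outside the network, pinned at -1), and the perturbed
#' node `gamma` to which beta is temporarily attached by an undirected
#' link of weight `beta_weight`. All remaining (normal) nodes update
#' synchronously by the distributed consensus protocol
#'
#' \deqn{x_u(t+1) = x_u(t) + \varepsilon \sum_{v \in N_u} S_{uv}\,(x_v(t) - x_u(t))}
#'
#' with step size `0 < epsilon < 1/W_max`, where `W_max` is the largest
#' total received influence weight in the beta-augmented system.
#'
#' @param leader node id of the leader (state +1).
#' @param perturbed node id gamma carrying the temporary beta link.
#' @param beta_weight weight of the beta--gamma link, in `(0, 1]`.
#' @param epsilon step size; `NULL` (default) means `0.9 / W_max` of the
#'   augmented system, chosen at run time.
#' @param tol convergence tolerance for the iterative path: iteration
#'   stops when the largest absolute state change falls below `tol`.
#' @param max_iter iteration cap for [simulate_competition()].
#' @return an object of class `competition_setup`.
#' @seealso [simulate_competition()], [solve_steady_state()]
#' @export
competition_setup <- function(leader, perturbed, beta_weight = 1,
                              epsilon = NULL, tol = 1e-10,
                              max_iter = 1e6) {
  if (!is.numeric(beta_weight) || beta_weight <= 0 || beta_weight > 1) {
    stop("beta_weight must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(epsilon) && (!is.numeric(epsilon) || epsilon <= 0)) {
    stop("epsilon must be positive (or NULL for the default)",
         call. = FALSE)
  }
  structure(list(leader = as.character(leader),
                 perturbed = as.character(perturbed),
                 beta_weight = beta_weight, epsilon = epsilon,
                 tol = tol, max_iter = max_iter),
            class = "competition_setup")
}

# Resolve the setup against a network influence matrix: augment with the
# beta link, locate the pinned nodes, pick/validate epsilon.
resolve_setup <- function(setup, mat) {
  stopifnot(inherits(setup, "competition_setup"),
            inherits(mat, "influence_matrix"))
  if (!setup$leader %in% mat$nodes) {
    stop("leader '", setup$leader, "' is not a network node", call. = FALSE)
  }
  aug <- augment_with_beta(mat, setup$perturbed, setup$beta_weight)
  bound <- epsilon_bound(aug)
  eps <- setup$epsilon
  if (is.null(eps)) eps <- if (is.finite(bound)) 0.9 * bound else 0.9
  if (eps >= bound) {
    stop("epsilon = ", eps, " violates the stability bound 1/W_max = ",
         bound, " (W_max = ", aug$W_max, ")", call. = FALSE)
  }
  n <- length(aug$nodes)
  list(aug = aug, eps = eps,
       leader_idx = match(setup$leader, aug$nodes),
       beta_idx = n,
       normal_idx = setdiff(seq_len(n), c(match(setup$leader, aug$nodes), n)))
}

#' One synchronous consensus update step
#'
#' Applies a single synchronous update of all normal nodes on a
#' beta-augmented influence matrix; the leader and the competitor keep
#' their pinned states +1 and -1. A node with no influencers is
#' unchanged (empty sum).
#'
#' @param setup a [competition_setup()].
#' @param state a list with `x` (named state vector over the augmented
#'   node set, competitor last under the reserved id `".beta"`) and step
#'   counter `t`.
#' @param mat the beta-augmented `influence_matrix` (as produced
#'   internally; obtainable via [partition_system()]'s `augmented`
#'   element).
#' @return the updated state list.
#' @export
step_states <- function(setup, state, mat) {
  stopifnot(inherits(mat, "influence_matrix"))
  x <- state$x
  if (!identical(names(x), mat$nodes)) {
    stop("state vector names must match the augmented node set",
         call. = FALSE)
  }
  bound <- epsilon_bound(mat)
  eps <- setup$epsilon
  if (is.null(eps)) eps <- if (is.finite(bound)) 0.9 * bound else 0.9
  if (eps >= bound) {
    stop("epsilon = ", eps, " violates the stability bound 1/W_max = ",
         bound, " (W_max = ", mat$W_max, ")", call. = FALSE)
  }
  li <- match(setup$leader, mat$nodes)
  bi <- match(BETA_ID, mat$nodes)
  if (is.na(bi)) stop("matrix lacks the competitor node; augment it first",
                      call. = FALSE)
  x_new <- x + eps * (drop(mat$S %*% x) - mat$D * x)
  x_new[c(li, bi)] <- c(1, -1)
  list(x = x_new, t = state$t + 1L)
}

#' Iterate the competition dynamics to its steady state
#'
#' Runs the synchronous consensus protocol from all-zero initial normal
#' states (the mean of the uniform random initialization; anchored nodes
#' converge to the same limit from any start in `[-1, 1]`) until the
#' largest absolute state change drops below `tol`. Nodes with no
#' influence chain to either competitor ("un-anchored") never move and
#' stay exactly 0.
#'
#' @param setup a [competition_setup()].
#' @param mat the network [to_influence_matrix()] (without the beta
#'   link; it is installed internally).
#' @param init optional named initial state vector over the network's
#'   normal nodes, each in `[-1, 1]`; default all zeros.
#' @return an object of class `steady_state`: list with `xbar` (named
#'   steady values of the normal nodes), `anchored` (logical, same
#'   names), `method = "iterative"`, `iterations`, and `residual` (last
#'   maximum state change).
#' @seealso [solve_steady_state()] for the closed-form path.
#' @export
simulate_competition <- function(setup, mat, init = NULL) {
  rs <- resolve_setup(setup, mat)
  aug <- rs$aug
  n <- length(aug$nodes)
  x <- numeric(n)
  names(x) <- aug$nodes
  if (!is.null(init)) {
    if (is.null(names(init)) ||
        !all(names(init) %in% aug$nodes[rs$normal_idx])) {
      stop("'init' must be named over the normal nodes", call. = FALSE)
    }
    if (any(abs(init) > 1)) {
      stop("initial states must lie in [-1, 1]", call. = FALSE)
    }
    x[names(init)] <- init
  }
  x[rs$leader_idx] <- 1
  x[rs$beta_idx] <- -1

  S <- aug$S
  D <- aug$D
  eps <- rs$eps
  normal <- rs$normal_idx
  it <- 0L
  delta <- Inf
  while (it < setup$max_iter) {
    x_new <- x + eps * (drop(S %*% x) - D * x)
    x_new[c(rs$leader_idx, rs$beta_idx)] <- c(1, -1)
    delta <- max(abs(x_new[normal] - x[normal]))
    x <- x_new
    it <- it + 1L
    if (delta < setup$tol) break
  }
  if (delta >= setup$tol) {
    stop("no convergence after ", setup$max_iter,
         " iterations (residual ", signif(delta, 3), ")", call. = FALSE)
  }
  anchored <- anchored_nodes(aug, rs$leader_idx, rs$beta_idx)[normal]
  structure(list(xbar = x[normal], anchored = anchored,
                 method = "iterative", iterations = it, residual = delta),
            class = "steady_state")
}

# Logical vector over the augmented node set: TRUE where the node lies
# downstream (in influence-flow direction) of a pinned competitor, i.e.
# a competitor is reachable by repeatedly following influencers.
anchored_nodes <- function(aug, leader_idx, beta_idx) {
  n <- length(aug$nodes)
  adj <- aug$S > 0  # adj[u, v]: v influences u
  reached <- logical(n)
  frontier <- c(leader_idx, beta_idx)
  reached[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  names(reached) <- aug$nodes
  reached
}

#' Closed-form steady state of the competition dynamics
#'
#' Solves the steady state directly instead of iterating. After
#' reordering so the two pinned competitors come last, the anchored
#' normal nodes satisfy the linear system
#' \deqn{(\bar D - \bar S)\,\bar x = c_\alpha\,(+1) + c_\beta\,(-1),}
#' where \eqn{\bar D, \bar S} are the normal-node blocks of the row-sum
#' diagonal and the influence matrix, and \eqn{c_\alpha, c_\beta} the
#' influence weights received from the leader and the competitor.
#' Un-anchored nodes (no influence chain to a competitor) are fixed at
#' 0; their columns drop out of the system while their weights remain in
#' \eqn{\bar D}. The result does not depend on the step size epsilon.
#'
#' @inheritParams simulate_competition
#' @return a `steady_state` object with `method = "closed_form"`.
#' @export
solve_steady_state <- function(setup, mat) {
  rs <- resolve_setup(setup, mat)
  aug <- rs$aug
  normal <- rs$normal_idx
  anchored_full <- anchored_nodes(aug, rs$leader_idx, rs$beta_idx)
  anchored <- anchored_full[normal]
  xbar <- numeric(length(normal))
  names(xbar) <- aug$nodes[normal]
  act <- normal[anchored]
  if (length(act)) {
    S <- aug$S
    M <- -S[act, act, drop = FALSE]
    diag(M) <- diag(M) + aug$D[act]
    rhs <- S[act, rs$leader_idx] - S[act, rs$beta_idx]
    sol <- tryCatch(solve(M, rhs), error = function(e) {
      stop("anchored subsystem unexpectedly singular: ",
           conditionMessage(e), call. = FALSE)
    })
    xbar[match(act, normal)] <- sol
  }
  structure(list(xbar = xbar, anchored = anchored,
                 method = "closed_form", iterations = 0L, residual = 0),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady_state (%s): %d normal nodes, %d anchored\n",
              x$method, length(x$xbar), sum(x$anchored)))
  print(round(x$xbar, 6))
  invisible(x)
}

#' Partitioned system blocks of the competition dynamics
#'
#' Exposes the algebra behind the closed form: the augmented system is
#' reordered so the two pinned competitors (leader, then beta) come
#' last, and partitioned into normal-node blocks `Dbar`, `Sbar`, the
#' competitor columns `c_alpha`, `c_beta` (influence received by normal
#' nodes from the competitors), rows `r_alpha`, `r_beta` and scalars
#' `d_alpha`, `d_beta` (influence on the competitors; inert because
#' their states are pinned, retained for completeness). From these:
#' `Q = I - epsilon (Dbar - Sbar)`, `B = epsilon [c_alpha c_beta]`, the
#' pinning indicator `H` (zero on competitors), and the full transition
#' matrix `T = I - epsilon H L` with Laplacian `L = D - S`. Every row of
#' `T` sums to 1; when all normal nodes are anchored the spectral radius
#' of `Q` is below 1 and the rows of
#' `(Dbar - Sbar)^{-1} [c_alpha c_beta]` are nonnegative and sum to 1,
#' which makes every steady state a convex combination of +1 and -1.
#'
#' @inheritParams simulate_competition
#' @return a list with the blocks named above, plus `order` (node ids,
#'   competitors last), `epsilon`, and `augmented` (the reordered
#'   beta-augmented `influence_matrix`).
#' @export
partition_system <- function(setup, mat) {
  rs <- resolve_setup(setup, mat)
  aug <- rs$aug
  ord <- c(rs$normal_idx, rs$leader_idx, rs$beta_idx)
  S <- aug$S[ord, ord, drop = FALSE]
  nodes <- aug$nodes[ord]
  n <- length(nodes)
  nn <- n - 2L
  D <- rowSums(S)
  L <- diag(D, n) - S
  H <- diag(c(rep(1, nn), 0, 0), n)
  eps <- rs$eps
  Tmat <- diag(n) - eps * (H %*% L)
  dimnames(Tmat) <- dimnames(S)
  Dbar <- D[seq_len(nn)]
  Sbar <- S[seq_len(nn), seq_len(nn), drop = FALSE]
  c_alpha <- S[seq_len(nn), nn + 1L]
  c_beta <- S[seq_len(nn), nn + 2L]
  Q <- diag(nn) - eps * (diag(Dbar, nn) - Sbar)
  B <- eps * cbind(alpha = c_alpha, beta = c_beta)
  list(order = nodes, epsilon = eps,
       Dbar = Dbar, Sbar = Sbar,
       c_alpha = c_alpha, c_beta = c_beta,
       r_alpha = S[nn + 1L, seq_len(nn)], r_beta = S[nn + 2L, seq_len(nn)],
       d_alpha = D[nn + 1L], d_beta = D[nn + 2L],
       Q = Q, B = B, H = H, L = L, T = Tmat,
       augmented = new_influence_matrix(S, nodes))
}

#' Map an opinion state to an expression level
#'
#' States live on `[-1, 1]` (support for the competitor vs the leader);
#' the corresponding normalized gene-expression level is the affine map
#' `y = (x + 1) / 2` onto `[0, 1]`.
#'
#' @param x numeric vector of states in `[-1, 1]`.
#' @return expression levels in `[0, 1]`.
#' @export
state_to_expression <- function(x) {
  if (any(!is.finite(x)) || any(x < -1) || any(x > 1)) {
    stop("states must lie in [-1, 1]", call. = FALSE)
  }
  (x + 1) / 2
}
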