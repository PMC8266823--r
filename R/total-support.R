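#' Steady value of one perturbed node
#'
#' Temporarily attaches the outside competitor beta to node `gamma` by
#' an undirected link of weight `beta_weight`, solves the closed-form
#' steady state with `alpha` as leader, and returns the perturbed node's
#' own steady value \eqn{\bar x_\gamma}. The link exists only for this
#' one evaluation; the input matrix is never modified.
#'
#' @param mat an [to_influence_matrix()] result.
#' @param alpha leader node id (state +1).
#' @param gamma perturbed node id; must differ from `alpha`.
#' @param beta_weight weight of the temporary beta link, in `(0, 1]`.
#' @return the scalar steady value of `gamma`, in `[-1, 1]`.
#' @seealso [total_support()], [solve_steady_state()]
#' @export
perturbed_steady_value <- function(mat, alpha, gamma, beta_weight = 1) {
  stopifnot(inherits(mat, "influence_matrix"))
  alpha <- as.character(alpha)
  gamma <- as.character(gamma)
  if (identical(alpha, gamma)) {
    stop("gamma must differ from the leader alpha", call. = FALSE)
  }
  for (id in c(alpha, gamma)) {
    if (!id %in% mat$nodes) stop("unknown node '", id, "'", call. = FALSE)
  }
  ss <- solve_steady_state(competition_setup(alpha, gamma, beta_weight), mat)
  unname(ss$xbar[gamma])
}

#' Total support of a candidate leader
#'
#' The total support of a leader `alpha` is
#' \deqn{ToS(\alpha) = \sum_{\gamma \in V \setminus \{\alpha\}} \bar x_\gamma,}
#' where \eqn{\bar x_\gamma} is the steady value of node gamma when the
#' outside competitor is attached to gamma (one attachment at a time,
#' each solved independently). It ranges over `[-(N-1), N-1]`; large
#' positive values mean the leader's +1 signal wins the tug-of-war at
#' most attachment points, which is the signature of a driver node.
#'
#' @inheritParams perturbed_steady_value
#' @return an object of class `support_score`: list with `leader`,
#'   `tos` (the total), and `per_gamma` (named vector of the
#'   \eqn{\bar x_\gamma} values).
#' @seealso [rank_drivers()]
#' @export
total_support <- function(mat, alpha, beta_weight = 1) {
  stopifnot(inherits(mat, "influence_matrix"))
  alpha <- as.character(alpha)
  if (!alpha %in% mat$nodes) stop("unknown node '", alpha, "'", call. = FALSE)
  per_gamma <- tos_per_gamma(mat, match(alpha, mat$nodes),
                             reach_closure(mat), beta_weight)
  structure(list(leader = alpha, tos = sum(per_gamma),
                 per_gamma = per_gamma),
            class = "support_score")
}

#' @export
print.support_score <- function(x, ...) {
  cat(sprintf("support_score: ToS(%s) = %.6g over %d perturbed nodes\n",
              x$leader, x$tos, length(x$per_gamma)))
  invisible(x)
}

# Inner loop shared by total_support / rank_drivers / the experiments:
# per-gamma steady values for one leader, using a precomputed influence
# reachability closure. For each gamma only the anchored normal nodes
# (downstream of alpha or of gamma, which carries the beta link) enter
# the linear system; beta shows up as +beta_weight on gamma's diagonal
# and -beta_weight on the right-hand side.
tos_per_gamma <- function(mat, alpha_idx, reach, beta_weight) {
  n <- length(mat$nodes)
  S <- mat$S
  D <- mat$D
  normals <- setdiff(seq_len(n), alpha_idx)
  Mbase <- -S[normals, normals, drop = FALSE]
  diag(Mbase) <- diag(Mbase) + D[normals]
  c_alpha <- S[normals, alpha_idx]
  anchored_by_alpha <- reach[alpha_idx, normals]
  out <- numeric(length(normals))
  names(out) <- mat$nodes[normals]
  for (j in seq_along(normals)) {
    g <- normals[j]
    aidx <- which(anchored_by_alpha | reach[g, normals])
    jpos <- match(j, aidx)
    M <- Mbase[aidx, aidx, drop = FALSE]
    M[jpos, jpos] <- M[jpos, jpos] + beta_weight
    rhs <- c_alpha[aidx]
    rhs[jpos] <- rhs[jpos] - beta_weight
    out[j] <- solve(M, rhs)[jpos]
  }
  out
}

# Total support of every node as trial leader; returns a named vector.
tos_all <- function(mat, beta_weight = 1, reach = reach_closure(mat)) {
  vapply(seq_along(mat$nodes), function(a) {
    sum(tos_per_gamma(mat, a, reach, beta_weight))
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(mat$nodes)
}

#' Rank candidate driver nodes by total support
#'
#' Evaluates every node as trial leader against the outside competitor,
#' computes its [total_support()], and ranks descending by score with
#' ties broken by node id (ascending). The top-`k` nodes are the
#' predicted driver / drug-target candidates; tied scores that straddle
#' the top-`k` boundary are reported rather than silently cut, since
#' equal-support leaders are indistinguishable to the model.
#'
#' @param net a [signaling_network()].
#' @param k number of top candidates to report (default 3).
#' @param beta_weight weight of the temporary competitor links.
#' @return an object of class `driver_ranking`: list with `scores` (data
#'   frame `node`, `tos`, `rank`, `tie_group`), `top_k` (character
#'   vector of length `min(k, N)`), `k`, and `boundary_tie` (`TRUE` when
#'   a tie group crosses the top-`k` cut).
#' @export
rank_drivers <- function(net, k = 3, beta_weight = 1) {
  stopifnot(inherits(net, "signaling_network"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (length(net$nodes) < 1L) stop("empty network", call. = FALSE)
  mat <- to_influence_matrix(net)
  tos <- tos_all(mat, beta_weight)
  ord <- order(-tos, names(tos))
  tos <- tos[ord]
  # tie groups: equal scores up to solver noise
  tg <- cumsum(c(TRUE, abs(diff(tos)) > 1e-9))
  scores <- data.frame(node = names(tos), tos = unname(tos),
                       rank = seq_along(tos), tie_group = tg,
                       stringsAsFactors = FALSE)
  kk <- min(k, nrow(scores))
  boundary_tie <- kk < nrow(scores) && tg[kk] == tg[kk + 1L]
  structure(list(scores = scores, top_k = scores$node[seq_len(kk)],
                 k = k, boundary_tie = boundary_tie),
            class = "driver_ranking")
}

#' @export
print.driver_ranking <- function(x, ...) {
  cat(sprintf("driver_ranking: top %d of %d nodes by total support\n",
              length(x$top_k), nrow(x$scores)))
  print(utils::head(x$scores, max(length(x$top_k), 5L)), row.names = FALSE)
  if (x$boundary_tie) {
    cat("note: a tie group straddles the top-k boundary\n")
  }
  invisible(x)
}
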