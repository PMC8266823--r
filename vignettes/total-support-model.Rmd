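---
title: "The outside-competition model and total-support ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The outside-competition model and total-support ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A disease signaling network is a heterogeneous graph $G(V, E)$ of $N$
genes and $M$ interactions: directed links (activation, inhibition,
expression, phosphorylation, ...) carry signal flow from source to
target, undirected links (binding/association, dissociation) act both
ways. `tosnet` encodes the wiring as a receiver-oriented influence
matrix $S$, where $S_{uv} \in (0, 1]$ is the weight with which node $v$
influences node $u$; a directed edge $a \to b$ sets $S_{ba} = w$, an
undirected edge sets both symmetric entries, and coincident directed
and undirected links add. Row sums $D_{uu} = \sum_v S_{uv}$ measure
total received influence and $W_{max} = \max_u D_{uu}$ bounds the
admissible update step.

The outside-competition dynamics pits a *leader* $\alpha \in V$ (a
candidate driver gene, state pinned at $+1$) against a *virtual
competitor* $\beta \notin V$ (an environmental agent such as a drug,
state pinned at $-1$) that is temporarily attached to one normal node
$\gamma$ at a time by an undirected link. Every other node follows the
synchronous consensus protocol

$$x_u(t+1) = x_u(t) + \varepsilon \sum_{v \in N_u} S_{uv}\,
  \bigl(x_v(t) - x_u(t)\bigr), \qquad 0 < \varepsilon < W_{max}^{-1},$$

a DeGroot-style averaging in which each gene drifts toward the weighted
mean of its influencers. States live on $[-1, 1]$; the affine map
$y = (x + 1)/2$ reads them as normalized expression levels. Because the
two competitors never yield, no global consensus forms: each normal
node settles at a steady value $\bar x_u \in [-1, 1]$ whose sign says
which competitor it ends up supporting.

### Steady states without iterating

Writing the update in matrix form $X(t+1) = (I - \varepsilon H L) X(t)$
with Laplacian $L = D - S$ and pinning indicator $H$ (zero rows for the
competitors), the normal-node block satisfies, in the limit,

$$\bar X = (\bar D - \bar S)^{-1}\,[\,c_\alpha\;c_\beta\,]
  \begin{bmatrix} +1 \\ -1 \end{bmatrix},$$

where $\bar D, \bar S$ are the normal-node blocks after reordering the
competitors last and $c_\alpha, c_\beta$ the influence weights received
from them. `solve_steady_state()` implements this directly and is the
production path; `simulate_competition()` iterates the protocol and
serves as the independent verification route. The closed form never
reads $\varepsilon$, which is why the tests can assert
$\varepsilon$-invariance of the limit.

The inversion is legitimate only on the *anchored* set: nodes from
which a pinned competitor can be reached by repeatedly following
influencers. `tosnet` computes that set by reverse reachability over
the influence graph and solves the linear system restricted to it.
Un-anchored nodes receive no information from either competitor; the
package fixes them at 0, the mean of the uniform random initial state,
which is also the exact limit of iteration started from all-zero
states. This makes the semantics of disconnected fragments well defined
without a convergence caveat. On fully anchored systems the rows of
$(\bar D - \bar S)^{-1}[c_\alpha\;c_\beta]$ are nonnegative and sum to
one, so every steady state is a convex combination of $+1$ and $-1$ —
the property the test suite asserts to $10^{-10}$.

### Total support and driver ranking

The total support of a candidate leader $\alpha$ is

$$ToS(\alpha) = \sum_{\gamma \in V \setminus \{\alpha\}} \bar x_\gamma,$$

where each $\bar x_\gamma$ comes from an *independent* solve with the
competitor attached to that $\gamma$ alone (links are not accumulated,
and only the perturbed node's own steady value enters the sum).
$ToS(\alpha)$ ranges over $[-(N-1), N-1]$: it is exactly $-(N-1)$ on an
edgeless network (every $\gamma$ hears only the competitor) and grows
with the leader's downstream coverage. `rank_drivers()` evaluates every
node as trial leader and sorts descending, ties broken by node id; the
top three (configurable `k`) are the driver / drug-target candidates,
and tie groups that straddle the cut are flagged rather than silently
truncated, because equal-support leaders are indistinguishable to the
model. Evaluating all leaders costs $N(N-1)$ linear solves of at most
$N{\times}N$; at the scale of curated pathway networks (50--170 nodes)
this completes in seconds on one CPU, helped by solving only the
anchored subsystem of each perturbation.

## Structural centralities

For validation the package computes, under hybrid hop-count traversal
(directed edges one way, undirected both ways, weights ignored):

* classic closeness $C_{clo}(u) = 1 / \sum_v d(u,v)$, reported as `NA`
  whenever some node is unreachable — the degeneracy that motivates the
  variant;
* the averaged-reciprocal closeness
  $C_{clo\text{-}v}(u) = \frac{1}{|V|-1}\sum_{v \neq u} 1/d(u,v)$,
  well defined on directed and disconnected networks, in $[0, 1]$ with
  the maximum attained exactly when $u$ reaches every node at distance
  1 (complete graphs, out-star hubs);
* reachability $N_R(u)$, the number of nodes reachable from $u$;
* hierarchical closeness $C_{hc}(u) = N_R(u) + C_{clo\text{-}v}(u)$,
  a lexicographic order — downstream coverage first, closeness as
  tiebreak — since the closeness term never exceeds 1;
* degree (incident edge count) and shortest-path betweenness on the
  same traversal semantics, as comparison baselines.

Distances and betweenness are delegated to `igraph` on the flow
digraph; the centrality formulas themselves are evaluated in-package.

## What the generators emulate

`generate_ba_directed()` grows a scale-free network by preferential
attachment: `m` seed nodes, the first newcomer attaching to all of
them, every later newcomer to `m` distinct nodes drawn proportionally
to total degree. Direction is assigned per edge uniformly at random
(the `orientation = "uniform"` rule), a deliberately neutral convention
that produces the nontrivial reachability variation the correlation
experiment needs; other orientation rules could be plugged in at the
same argument. With $n = 50$ the edge count is exactly $49$ at $m = 1$
and $96$ at $m = 2$, so an ensemble drawing $m$ uniformly from
$\{1, 2\}$ per network stays inside the 49--100 band by construction,
with no edge pruning. The generator reproduces hub-dominated degree
structure but none of the biological texture of curated pathways:
no undirected binding links, no weight heterogeneity, no modular or
bow-tie organisation. Passing ensemble tests therefore validates the
model's behaviour on scale-free topology, not its biological
predictions.

`make_demo_network()` is a deterministic 12-gene, 19-interaction
fixture at the scale of a small disease network, with `g01` wired as
the natural driver; its `"weighted"` variant changes only a handful of
weights yet flips the steady-state sign of several genes, illustrating
how strongly adjacency weights shape competition outcomes. The wiring
is a synthetic emulation of that scale, not a reconstruction of any
published network. `make_kgml_fixture()` writes small well-formed KGML
(gene entries, paralogous multi-gene entries, complex groups, directed
and undirected relation subtypes) so that the KGML reader is exercised
without any KEGG download.

## The correlation experiment

`correlation_experiment()` generates the 100-network ensemble
($n = 50$, $m \in \{1, 2\}$, all seeds derived from one master seed),
computes $ToS$ for every node of every network, and correlates it with
$C_{clo\text{-}v}$ and $C_{hc}$. Two aggregates are computed: the mean
of per-network Pearson r and the pooled r over all 5000
(node, network) pairs. The package reports the **pooled** aggregate as
its primary ensemble statistic. The reasons are structural: it uses
every node-level observation, it is insensitive to occasional
degenerate networks, and — decisively — it treats the two centralities
symmetrically: on these ensembles the pooled correlations of closeness
and hierarchical closeness agree to within a few thousandths
(both ≈ 0.79 at the default settings, as `scripts/acceptance.R`
recomputes), mirroring the reference observation that both centralities
correlate with total support at the same level, whereas the per-network
means separate them (≈ 0.82 vs ≈ 0.66). The separation has a clean
cause: $C_{hc}$ is dominated by the raw reach count, whose relation to
$ToS$ saturates — support decays with distance, so far-downstream nodes
add reach but little support — while the inverse-distance weighting of
$C_{clo\text{-}v}$ matches that decay and stays closer to linear.
Per-network r values, both aggregates and their significance levels are
all retained in the result object.

`compare_centralities()` reports, for one network, the champions of
hierarchical closeness, degree and betweenness together with their
total support; the shipped contrast fixtures (frozen generator seeds)
show the closeness champion beating the degree and betweenness
champions, the qualitative pattern that motivates using closeness-type
measures for driver prediction.

## Numerical choices and limitations

* Iteration: all-zero start, stop when the largest state change is
  below `tol` (default $10^{-10}$), cap $10^6$ steps; default step
  $\varepsilon = 0.9 / W_{max}$ of the augmented system. Near the
  bound's lower range convergence is slow, so property tests that sweep
  $\varepsilon$ tighten `tol` to $10^{-13}$.
* The closed-form path raises an internal error if the anchored
  subsystem is singular — impossible when anchoring is computed
  correctly, so it is treated as a bug signal rather than a user error.
* Ties in rankings and champion selection break lexicographically by
  node id; equal-$ToS$ groups are reported explicitly.
* Edge weights must lie in $(0, 1]$; inhibition is represented
  topologically (a directed link), not by sign — negative weights are
  out of scope.
* The competitor's backward half of its undirected link (influence of
  $\gamma$ on $\beta$) is inert because $\beta$'s state is pinned; the
  blocks describing it are retained in `partition_system()` only to
  test the algebra.
* KGML coverage is pragmatic: gene entries, groups, relations. The
  reader resolves paralogous multi-gene entries into one node per gene
  identifier (no intra-entry edges, unlike complexes), ignores
  standalone compound/map entries with a warning, and keeps unlisted
  relation subtypes as directed links with a warning. Curation against
  pathway images, compound modelling and sign semantics are out of
  scope.
* Problem sizes in the shipped tests: property suites run on networks
  of 3--12 nodes (100 seeded topologies), the ensemble experiment on
  100 networks of 50 nodes; the full test suite and the acceptance
  script each complete in about a minute on one CPU.
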