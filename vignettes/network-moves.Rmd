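---
title: "Rearrangement moves on the tiers of phylogenetic network space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rearrangement moves on the tiers of phylogenetic network space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailmoves)
```

## The model

A rooted binary phylogenetic network on a taxon set $X$ is a directed
acyclic graph without parallel arcs in which one node is the root
(indegree 0, outdegree 1) and every other node is a leaf (1, 0), a tree
node (1, 2) or a reticulation (2, 1); the leaves are labelled bijectively
by $X$. The reticulation number $k = |E| - |V| + 1$ counts the
reticulations, and the *tier* $(n, k)$ — all networks on $n$ taxa with $k$
reticulations — is the natural unit of search space, because optimisation
scores are not comparable across reticulation numbers. Degree counting
forces $|V| = 2n + 2k$ and $|E| = 2n + 3k - 1$ throughout a tier, which
the package asserts after every operation (`tier_signature()`).

Unlike trees, networks can give a pair of nodes several *lowest* common
ancestors; `lca_set()` returns the minimal common ancestors (pairwise
incomparable, never empty), and all constructions that need "an LCA" take
the canonically least member.

Node identity is never meaningful: networks compare through
label-preserving isomorphism (`is_isomorphic()`) or through
`canonical_form()` tokens, which are backed by BLISS canonical labelling
on the directed graph with leaves coloured by taxon rank. Canonical-token
equality is tested to coincide exactly with pairwise isomorphism on
exhaustively enumerated tiers.

## Moves

A *tail move* of edge $(u, v)$ to edge $f$ deletes $(u, v)$, subdivides
$f$ with a new node, suppresses the freed degree-2 node $u$, and
reattaches; a *head move* does the same with the head $v$, and is only
possible when $v$ is a reticulation. rSPR = head or tail; the distance-$d$
class of a move measures, after the subdivision step, the undirected
distance from the moved endpoint to its new position; rNNI = distance-1
rSPR. One convention worth stating: we rename the subdivision node to the
id of the suppressed node after every move, so a move never changes the
node set and the moved endpoint keeps its id. This makes recorded inverse
moves and sequence bookkeeping exact at the id level (not merely up to
isomorphism) and costs nothing semantically.

Validity is characterised in closed form: a tail move needs a *movable*
edge (tail not the root, not a reticulation, and no triangle-induced
parallel edge), a target not below the moving head, and a target head
different from the moving head. Two refinements emerged when we tested
this characterisation against the independent apply-then-validate oracle
(`oracle_move_valid()`, which runs the four defining steps literally on
arbitrary arc pairs and validates the result):

- when the tail sits in a triangle (parent $p$, other child $c$, long edge
  $(p, c)$ present), relocating it onto $(p, u)$, $(u, c)$ or $(p, c)$
  itself still yields a valid — isomorphic — network, because the target
  is subdivided before the suppression; the generic "movability" condition
  would wrongly refuse these three trivial moves;
- symmetrically for head moves when the target is incident to the moving
  head's other parent edge, child edge, or their long edge.

We treat "the result is a valid network" as the authoritative contract and
accept these trivial moves; the check-versus-oracle agreement is asserted
on *every* ordered arc pair of *every* network of tiers (2,1), (3,1) and
(2,2), so any divergence is a test failure rather than a tie-break. Note
also that relocating an endpoint onto an adjacent edge is a
*distance-0* move under the definition above (the subdivision node is one
step away); all distance-0 moves are trivial, and the rNNI classes filter
on distance exactly 1.

## Simulating head moves by tail moves

Tail moves alone connect every tier — head moves are dispensable — except
for one two-taxon case. The engine is the replacement of any valid
distance-1 head move by at most four tail moves when $n \ge 2$.
`classify_head1()` recognises the six local patterns (sideways below a
tree node / above a reticulation, downward or upward through a tree node
or reticulation) by which neighbour the moving head shares with its
target, and flags the degenerate coincidences; every flagged degeneracy is
tested to produce an isomorphic network, in which case the simulation is
the empty sequence. The figure-level constructive sequences are only
partially printed in the source text, so the package uses (per design):
the one-move shortcut for the downward-through-a-tree-node case (move the
tree node's other child edge onto the moving head's other parent edge —
derived and verified against the head-move result), and bounded
bidirectional BFS over tail moves (cap 4) for everything else. For
one-leaf networks no length bound is claimed; the cap is raised adaptively
(4, 6, 8) and failure is reported honestly.

The **exceptional networks** are found by enumeration, not by name: the
two-leaf tier-1 network (a triangle over a cherry — in fact *every*
tier-(2,1) network has this shape, the two isomorphism classes differing
only in which leaf hangs off the triangle) admits no nontrivial tail move
at all, so its single nontrivial head move cannot be simulated
(`simulate_head1()` raises an `exceptional_network` error); the one-leaf
tier-2 network admits only isomorphic-result head moves.

## Constructive connectivity: the frontier algorithm

`tail_connect()` and `rspr_connect()` grow downward-closed node sets $Y$,
$Y'$ in evolving copies of the source and target networks, together with
an isomorphism between the induced subgraphs, starting from the leaves
matched by label. Each extension adds one node pair after at most three
tail moves (giving the $3(n + 2k)$ bound) or, with head moves allowed, at
most one move per reticulation and two per tree node (giving
$2n + 3k - 1$). The case tree follows the inductive proof: a lowest
unmatched reticulation on the target side is replicated on the source side
(zero moves if already present, two tail moves to slide a reticulation
over the right child, three when a triangle blocks the sliding); the
symmetric case acts on the target copy, with every move recorded alongside
its inverse; when all lowest nodes are tree nodes, the two relevant
children are given a common parent by at most two tail moves.

Design choices the construction leaves open:

- *Tie-breaking.* "Any lowest node", "any LCA", "any movable edge" are
  resolved by canonical node order, making the emitted sequences
  deterministic and testable.
- *Target-side bookkeeping.* Moves applied to the target copy are emitted
  at the end, inverted and in reverse order, translated onto the source
  chain through the final isomorphism; the emitted sequence therefore acts
  on the source network only, and the package replays it and asserts the
  final isomorphism before returning.
- *The root-triangle swap.* One sub-case (the blocking triangle hangs off
  the root) needs a three-tail-move sequence equivalent to a head move of
  the triangle's long edge. We derived explicit sequences for both
  orientations (the swapped subtree a tree node, or the reticulation child
  a tree node) and fall back to a cap-3 BFS plus isomorphism
  reconciliation on degenerate coincidences; either way the three-move
  budget is preserved.
- *Exclusions.* `tail_connect()` refuses the exceptional networks above
  (error class `excluded_instance`); `rspr_connect()` has no exclusions
  and connects the exceptional pair with a single head move.

`decompose_tail_move()` replaces one valid tail move of $(u,v)$ to
$(s,t)$ by at most $n + 3k - 1$ distance-1 moves: the tail slides edge by
edge up a shortest directed path from $u$ to a lowest common ancestor of
$u$ and $s$, then down to $s$. When $s$ is that ancestor itself the final
target already lies on the path and the hop list is truncated there; hops
onto the current parent edge (distance 0) are skipped. Every intermediate
move is validity-checked and the composite is asserted isomorphic to the
direct application.

## Unrooted networks, rootability, orientation

An unrooted binary network is a connected simple graph with nodes of
degree 1 (labelled leaves) and 3. It is *rootable* — orientable as a
rooted network with a chosen leaf as root — exactly when no cut-edge has a
leafless side, equivalently when no blob (non-trivial biconnected
component) is incident to exactly one cut-edge (a *redundant terminal
component*). `orient()` directs cut-edges away from the root leaf and
gives each blob a bipolar orientation from its entry node to a chosen exit
node. We compute the bipolar numbering through an open ear decomposition:
the first ear is a cycle through entry and exit (two internally
vertex-disjoint paths, found by two augmentation rounds on the node-split
unit-capacity digraph), and each further ear's internal path is inserted
as a block next to its earlier endpoint, which keeps one earlier and one
later neighbour for every internal node. The exit node is the
canonically least node incident to an outgoing cut-edge (any choice is
valid).

Degree arithmetic forces every redundant terminal component to have an odd
number of nodes, at least 5, and edge excess $|E'| - |V'| = (|V'|+1)/2
\ge 3$; `terminal_component_candidates()` certifies the minima by
exhaustive backtracking over degree sequences, and
`strip_terminal_component()` removes one component with a single SPR move
(relocating the component-side neighbour of the cut-edge onto the
canonically least leaf edge), which the tests show is at exact SPR
distance 1. `spr_connect()` strips both networks rootable (at most
$\lfloor k/3 \rfloor$ moves each), orients both at the same canonically
least taxon, and runs the frontier algorithm in `spr` mode, where the
blocked-triangle case is resolved either by re-orienting the triangle's
bottom edge — free at the unrooted level, it only changes the rooted view
— or by one target-side tail move; this yields at most one SPR move per
added node and the overall $n + \frac{8}{3}k$ bound.

## Oracles and synthetic data

The test suite never trusts a construction it can cross-check:

- *Tier enumeration.* The primary enumerator is BFS closure under rSPR
  moves from one deterministic representative, exhaustive because every
  tier is connected under rNNI moves (a strictly smaller move class). An
  independent constructive enumerator adds one reticulation in all ways to
  every network of the tier below; it equals the closure for $k \le 1$ but
  is provably incomplete at $k = 2$ (the one-leaf tier-2 network admits no
  reticulation-edge deletion whose suppression stays simple — it only
  exists "from above"), so the cross-check asserts containment plus
  equality where equality holds. Enumerated sizes: tier (2,1) has 2
  classes, (1,2) has 1, (3,1) has 21, (2,2) has 18, (3,2) has 279.
- *Exact distances.* Bidirectional BFS with canonical deduplication, with
  explicit depth and node caps that return "gave up" rather than a wrong
  answer; unreachability (the tail-move graph of tier (2,1)) is detected
  by component exhaustion.
- *Agreement forests.* On trees, the rSPR distance equals the size of a
  maximum agreement forest minus one; `maf_size_exhaustive()` exhausts all
  partitions of $X \cup \{\rho\}$ (guarded to $n \le 6$, Bell(7) = 877
  partitions) and is tested to match the BFS distance on all pairs of
  four-leaf trees. Node-disjointness of the restricted subtrees is judged
  on the *unsuppressed* path unions — judging it after suppression admits
  spurious forests and underestimates distances. Glued into a mycorrhizal
  forest (tree components hanging off a fixed biconnected root component),
  the tail and rSPR distances both collapse to the sum of per-component
  tree distances, which the suite verifies on toy instances; this identity
  is what makes shortest-sequence computation NP-hard, and is why the
  package only promises bounded sequences.

`random_network(n, k, seed)` is the synthetic generator: a
uniform-attachment random binary tree followed by $k$ reticulation
additions, each subdividing a uniformly random ordered pair of distinct
edges and connecting the subdivision nodes, rejecting and resampling
invalid results (bounded retries). This emulates the regime the theory
addresses — uniform-ish dense tiers at small $n$ and $k$ — and the
connectivity batteries run it at tiers (3,1), (4,2) and (5,2) with 100
seeded pairs each, the scale at which every code path (including the rare
triangle cases) is exercised while the whole suite stays within minutes.
It does **not** emulate biological shape distributions (no birth–death
branch lengths, no tree-child or level-constrained structure), so a green
suite establishes correctness and the proven bounds, not performance on
empirically realistic networks. The generator restores the caller's RNG
state; a single integer seed reproduces every fixture.

## Numerical and degenerate-input choices

- All searches and constructions break ties by canonical node order
  (id length, then lexicographic), so outputs are deterministic.
- Parsing: extended Newick with `#H<k>` hybrid tags, each tag appearing
  exactly twice; plain Newick accepted for trees (a root edge is added);
  branch lengths and internal labels are discarded with a warning;
  multifurcations are an error unless `resolve = TRUE` (left-comb).
- Degenerate tiers: $(1, 1)$ is empty (the lone reticulation cannot find
  two distinct parents) and `enumerate_tier(1, 1)` returns an empty list;
  one-leaf tiers start from the hand-built $(1, 2)$ fixture.
- `is_exceptional_network()` identifies the excluded networks
  structurally (isomorphism after label anonymisation), never by node
  names or taxa.

## Known limitations

- No shortest-sequence computation (NP-hard) and no fixed-parameter or
  approximation algorithms; the BFS oracles are toy-scale by design.
- The $O(n^2)$ distance-1 bounds are realised by composing
  `tail_connect()` with `decompose_tail_move()`; no dedicated rNNI-chain
  construction is provided.
- Vertical moves (changing $k$), non-binary networks and branch lengths
  are out of scope; chain/cluster/subtree reduction safety is not
  addressed.
- Diameter *lower*-bound constructions are not implemented; lower bounds
  are only witnessed empirically by the exact BFS distances.
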