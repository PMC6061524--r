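# tailmoves

Rearrangement moves and tier connectivity for binary phylogenetic networks.

Phylogenetic networks generalise phylogenetic trees to reticulate evolution
(hybridisation, horizontal gene transfer, recombination): a rooted binary
network is a leaf-labelled DAG whose internal nodes either split lineages
(tree nodes, indegree 1 / outdegree 2) or merge them (reticulations,
indegree 2 / outdegree 1). Search heuristics over network space need
rearrangement moves, the network analogues of rooted subtree-prune-regraft
(rSPR): a **tail move** relocates the tail of one directed edge onto
another edge, a **head move** relocates the head of a reticulation edge;
distance-1 versions of both are the rNNI moves, and SPR/NNI are the
unrooted analogues. Because adding reticulations always improves fit,
searches are organised by **tier**: the set of networks on a taxon set X
with fixed reticulation number k = |E| − |V| + 1.

This package is for people building or studying such searches. It provides:

- the rooted and unrooted network model with validation, tier arithmetic,
  label-preserving isomorphism and canonical forms, multi-LCA ancestry
  queries, extended-Newick / JSON / edge-list I/O;
- validity checking, application, inversion, distance classification and
  enumeration of tail / head / rSPR / rNNI / SPR moves, with an
  apply-then-validate oracle used to cross-check the closed-form validity
  conditions;
- simulation of any distance-1 head move by at most four tail moves (the
  single two-leaf, one-reticulation exception is detected and refused);
- constructive same-tier connectivity: `tail_connect()` emits a verified
  sequence of at most `3(n + 2k)` tail moves, `rspr_connect()` at most
  `2n + 3k − 1` rSPR moves, `spr_connect()` at most `n + (8/3)k` SPR moves
  on unrooted networks, and `decompose_tail_move()` splits one tail move
  into at most `n + 3k − 1` distance-1 moves;
- rootability testing (no redundant cut-edges), bipolar orientation at any
  leaf, redundant terminal components and their constructive removal;
- toy-scale oracles: exhaustive tier enumeration (two independent
  enumerators), exact move distances by bidirectional BFS with canonical
  deduplication, exhaustive maximum-agreement-forest computation, and
  mycorrhizal-forest gadgets for which tail, rSPR and per-tree-SPR
  distances coincide.

Finding *shortest* tail or rSPR sequences is NP-hard; the package
deliberately offers bounded constructive sequences plus exact BFS oracles
at toy scale, not a shortest-path solver.

## Worked example

```r
library(tailmoves)
A <- random_network(4, 2, seed = 11)   # tier (n = 4, k = 2)
B <- random_network(4, 2, seed = 12)
write_enewick(A)
#> ((((x3)#H1,(x1,((#H1,(x2,x4)))#H2)),#H2));
tier_signature(A)
#> tier (n = 4, k = 2): 12 nodes, 13 edges

seqm <- tail_connect(A, B)             # bound: 3(n + 2k) = 24 moves
length(seqm)
#> [1] 5
seqm[[1]]
#> tail move: (v1,L2) -> (n4,L3)
is_isomorphic(replay_moves(A, seqm), B)$isomorphic
#> [1] TRUE
exact_distance(A, B, "rspr", cap = 4)  # exact BFS oracle at toy scale
#> [1] 3
```

The constructed sequence turns `A` into a network isomorphic to `B` in 5
tail moves (every prefix is a valid tier-(4,2) network); the true rSPR
distance for this pair is 3, so the construction is close to optimal here
while guaranteeing the linear bound in general.

Unrooted networks need not be orientable as rooted ones:

```r
U <- unrootable_fixture()              # 5-node terminal component + 3 leaves
is_rootable(U)
#> [1] FALSE
st <- strip_terminal_component(U)      # one constructive SPR move
is_rootable(st$net)
#> [1] TRUE
exact_spr_distance(U, st$net, cap = 3)
#> [1] 1
```

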