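#' Rooted binary phylogenetic network
#'
#' Constructs a rooted binary phylogenetic network on a taxon set X: a
#' directed acyclic graph without parallel arcs in which every node is the
#' root (indegree 0, outdegree 1), a tree node (1, 2), a reticulation (2, 1)
#' or a leaf (1, 0), and the leaves are labelled bijectively by X. Node ids
#' are opaque strings; two networks are compared through [canonical_form()]
#' or [is_isomorphic()], never through their ids.
#'
#' @param arcs two-column character matrix of arcs `(tail, head)`.
#' @param labels named character vector mapping leaf node ids to taxa.
#' @param validate if `TRUE` (default), stop on an invalid network.
#' @return an object of class `rooted_network` with fields `nodes`, `arcs`,
#'   `labels`.
#' @examples
#' net <- rooted_network(
#'   rbind(c("rho", "a"), c("a", "x"), c("a", "y")),
#'   c(x = "x", y = "y")
#' )
#' tier_signature(net)
#' @export
rooted_network <- function(arcs, labels, validate = TRUE) {
  arcs <- as_arc_matrix(arcs)
  labels <- as_label_vector(labels)
  net <- structure(
    list(
      nodes = sort_nodes(unique(c(arcs, names(labels)))),
      arcs = arcs,
      labels = labels
    ),
    class = "rooted_network"
  )
  if (validate) {
    bad <- validate_rooted(net)
    if (length(bad) > 0) {
      stop("invalid rooted network: ", paste(bad, collapse = "; "))
    }
  }
  net
}

as_arc_matrix <- function(arcs) {
  if (is.null(arcs) || length(arcs) == 0) {
    return(matrix(character(0), ncol = 2))
  }
  arcs <- matrix(as.character(arcs), ncol = 2)
  colnames(arcs) <- NULL
  arcs
}

as_label_vector <- function(labels) {
  labels <- vapply(labels, as.character, character(1))
  if (is.null(names(labels)) || any(names(labels) == "")) {
    stop("labels must be a named vector (node id -> taxon)")
  }
  labels
}

# deterministic node order: by id length then lexicographic, so generated
# ids n1, n2, ..., n10 sort numerically
sort_nodes <- function(ids) {
  ids[order(nchar(ids), ids)]
}

#' @export
print.rooted_network <- function(x, ...) {
  ts <- try(tier_signature(x), silent = TRUE)
  if (inherits(ts, "try-error")) {
    cat("<rooted_network: invalid,", length(x$nodes), "nodes,",
        nrow(x$arcs), "arcs>\n")
  } else {
    cat(sprintf("<rooted_network: %d leaves, %d reticulations, %d nodes, %d arcs>\n",
                ts$n_leaves, ts$k, ts$n_nodes, ts$n_edges))
  }
  invisible(x)
}

net_index <- function(net) {
  ch <- split(net$arcs[, 2], factor(net$arcs[, 1], levels = net$nodes))
  pa <- split(net$arcs[, 1], factor(net$arcs[, 2], levels = net$nodes))
  list(children = ch, parents = pa)
}

net_children <- function(net, v) net$arcs[net$arcs[, 1] == v, 2]
net_parents <- function(net, v) net$arcs[net$arcs[, 2] == v, 1]

net_root <- function(net) {
  indeg <- table(factor(net$arcs[, 2], levels = net$nodes))
  net$nodes[indeg == 0]
}

net_leaves <- function(net) {
  outdeg <- table(factor(net$arcs[, 1], levels = net$nodes))
  net$nodes[outdeg == 0]
}

net_reticulations <- function(net) {
  indeg <- table(factor(net$arcs[, 2], levels = net$nodes))
  net$nodes[indeg == 2]
}

net_tree_nodes <- function(net) {
  indeg <- table(factor(net$arcs[, 2], levels = net$nodes))
  outdeg <- table(factor(net$arcs[, 1], levels = net$nodes))
  net$nodes[indeg == 1 & outdeg == 2]
}

has_arc <- function(net, u, v) {
  any(net$arcs[, 1] == u & net$arcs[, 2] == v)
}

fresh_node_id <- function(net, n = 1L) {
  i <- 1L
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0("n", i)
    if (!(cand %in% net$nodes) && !(cand %in% out)) out <- c(out, cand)
    i <- i + 1L
  }
  out
}

#' Validate a rooted binary phylogenetic network
#'
#' Checks all defining invariants and returns a character vector of
#' violations (empty means valid): acyclicity, absence of parallel arcs,
#' a unique root of indegree 0 and outdegree 1, binary degree constraints on
#' every other node, bijective leaf labelling, and the tier node/edge count
#' identities.
#'
#' @param net a `rooted_network` (possibly built with `validate = FALSE`).
#' @return character vector of human-readable violations; `character(0)` if
#'   the network is valid.
#' @export
validate_rooted <- function(net) {
  bad <- character(0)
  arcs <- net$arcs
  nodes <- net$nodes
  if (nrow(arcs) == 0) return("no arcs: a network has at least a root edge")
  key <- paste(arcs[, 1], arcs[, 2])
  if (anyDuplicated(key)) bad <- c(bad, "parallel arcs")
  if (any(arcs[, 1] == arcs[, 2])) bad <- c(bad, "self-loop")
  indeg <- table(factor(arcs[, 2], levels = nodes))
  outdeg <- table(factor(arcs[, 1], levels = nodes))
  roots <- nodes[indeg == 0]
  if (length(roots) != 1) {
    bad <- c(bad, sprintf("expected exactly one indegree-0 node, found %d",
                          length(roots)))
  } else if (outdeg[[roots]] != 1) {
    bad <- c(bad, "root must have outdegree 1")
  }
  for (v in nodes) {
    di <- indeg[[v]]; do <- outdeg[[v]]
    if (length(roots) == 1 && v == roots) next
    ok <- (di == 1 && do == 0) || (di == 1 && do == 2) || (di == 2 && do == 1)
    if (!ok) {
      bad <- c(bad, sprintf("node %s has indegree %d outdegree %d", v, di, do))
    }
  }
  # cycle check: Kahn's algorithm
  if (!is_acyclic(arcs, nodes)) bad <- c(bad, "cycle")
  leaves <- nodes[outdeg == 0 & indeg > 0]
  if (!setequal(names(net$labels), leaves)) {
    bad <- c(bad, "leaf labels must cover exactly the leaves")
  }
  if (anyDuplicated(net$labels)) bad <- c(bad, "duplicate taxon labels")
  bad
}

is_acyclic <- function(arcs, nodes) {
  indeg <- table(factor(arcs[, 2], levels = nodes))
  indeg <- stats::setNames(as.integer(indeg), nodes)
  queue <- nodes[indeg == 0]
  seen <- 0L
  ch <- split(arcs[, 2], factor(arcs[, 1], levels = nodes))
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (w in ch[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(nodes)
}

#' Tier signature of a network
#'
#' The tier of a network is determined by its leaf count n and reticulation
#' number k = |E| - |V| + 1. For binary networks every member of tier (n, k)
#' has exactly 2n + 2k nodes and 2n + 3k - 1 edges, so the full signature is
#' redundant but convenient for conservation checks.
#'
#' @param net a valid `rooted_network`.
#' @return list of class `tier_signature` with `n_leaves`, `k`, `n_nodes`,
#'   `n_edges`.
#' @export
tier_signature <- function(net) {
  bad <- validate_rooted(net)
  if (length(bad) > 0) stop("invalid network: ", paste(bad, collapse = "; "))
  n_nodes <- length(net$nodes)
  n_edges <- nrow(net$arcs)
  k <- n_edges - n_nodes + 1L
  n <- length(net$labels)
  stopifnot(n_nodes == 2 * n + 2 * k, n_edges == 2 * n + 3 * k - 1)
  structure(list(n_leaves = n, k = k, n_nodes = n_nodes, n_edges = n_edges),
            class = "tier_signature")
}

#' @export
print.tier_signature <- function(x, ...) {
  cat(sprintf("tier (n = %d, k = %d): %d nodes, %d edges\n",
              x$n_leaves, x$k, x$n_nodes, x$n_edges))
  invisible(x)
}

same_tier <- function(a, b) {
  ta <- tier_signature(a); tb <- tier_signature(b)
  ta$n_leaves == tb$n_leaves && ta$k == tb$k &&
    setequal(a$labels, b$labels)
}

#' Ancestry queries
#'
#' `is_above(net, u, v)` tests whether `u` lies weakly above `v`, i.e.
#' whether there is a (possibly empty) directed path from `u` to `v`.
#' `descendant_set` returns all nodes weakly below `u`.
#'
#' @param net a `rooted_network`.
#' @param u,v node ids.
#' @return `is_above`: logical. `descendant_set`: character vector.
#' @export
is_above <- function(net, u, v) {
  check_node(net, u); check_node(net, v)
  v %in% descendant_set(net, u)
}

#' @rdname is_above
#' @export
descendant_set <- function(net, u) {
  check_node(net, u)
  ch <- split(net$arcs[, 2], factor(net$arcs[, 1], levels = net$nodes))
  seen <- stats::setNames(logical(length(net$nodes)), net$nodes)
  stack <- u
  while (length(stack) > 0) {
    x <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[[x]]) next
    seen[[x]] <- TRUE
    stack <- c(stack, ch[[x]])
  }
  net$nodes[seen]
}

check_node <- function(net, u) {
  if (!(u %in% net$nodes)) stop("unknown node id: ", u)
  invisible(TRUE)
}

# full reflexive reachability: named list node -> character vector of
# weak descendants; used by hot paths (move checking / enumeration)
reach_table <- function(net) {
  ch <- split(net$arcs[, 2], factor(net$arcs[, 1], levels = net$nodes))
  # process in reverse topological order
  ord <- topo_order(net)
  desc <- vector("list", length(net$nodes))
  names(desc) <- net$nodes
  for (v in rev(ord)) {
    d <- v
    for (w in ch[[v]]) d <- c(d, desc[[w]])
    desc[[v]] <- unique(d)
  }
  desc
}

topo_order <- function(net) {
  arcs <- net$arcs; nodes <- net$nodes
  indeg <- table(factor(arcs[, 2], levels = nodes))
  indeg <- stats::setNames(as.integer(indeg), nodes)
  ch <- split(arcs[, 2], factor(arcs[, 1], levels = nodes))
  queue <- nodes[indeg == 0]
  out <- character(0)
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (w in ch[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) stop("cycle: no topological order")
  out
}

#' Lowest common ancestors
#'
#' In a network a pair of nodes can have several lowest common ancestors.
#' `lca_set` returns the minimal common ancestors of `u` and `v`: common
#' ancestors none of whose proper descendants is also a common ancestor.
#' The set is never empty (the root is always a common ancestor) and its
#' members are pairwise incomparable.
#'
#' @param net a `rooted_network`.
#' @param u,v node ids.
#' @return character vector of node ids, in canonical node order.
#' @export
lca_set <- function(net, u, v) {
  check_node(net, u); check_node(net, v)
  reach <- reach_table(net)
  common <- net$nodes[vapply(
    net$nodes, function(a) u %in% reach[[a]] && v %in% reach[[a]], logical(1)
  )]
  minimal <- common[vapply(common, function(a) {
    below <- setdiff(reach[[a]], a)
    !any(common %in% below)
  }, logical(1))]
  sort_nodes(minimal)
}
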