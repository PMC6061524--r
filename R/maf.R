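# Agreement forests on rooted trees and the mycorrhizal-forest gadget.
# On trees the rSPR distance equals the size of a maximum agreement forest
# minus one, which provides an independent oracle for move distances; glued
# into a fixed biconnected root component (a mycorrhizal forest), the
# per-tree distances add up, which is the NP-hardness gadget for tail and
# rSPR distances on networks.

#' Restrict a tree to a taxon subset
#'
#' Computes `T|_Y`: the union of the pairwise paths between the chosen
#' nodes, with all indegree-1 outdegree-1 nodes suppressed. `Y` is a set of
#' taxa, optionally including the string `"rho"` to denote the root.
#'
#' @param tree a valid `rooted_network` with no reticulations.
#' @param Y character vector of taxa (and/or `"rho"`).
#' @return an object of class `restricted_tree`: list with `arcs`, `labels`
#'   (taxa plus `"rho"` when included) and `span` (the node set of the
#'   path union inside `tree`, used for node-disjointness checks).
#' @export
restrict_tree <- function(tree, Y) {
  stopifnot(length(net_reticulations(tree)) == 0)
  rho <- net_root(tree)
  sel <- character(0)
  labels <- character(0)
  for (yy in Y) {
    if (yy == "rho") {
      sel <- c(sel, rho)
      labels[rho] <- "rho"
    } else {
      nd <- names(tree$labels)[match(yy, tree$labels)]
      if (is.na(nd)) stop("unknown taxon: ", yy)
      sel <- c(sel, nd)
      labels[nd] <- yy
    }
  }
  par <- stats::setNames(rep(NA_character_, length(tree$nodes)), tree$nodes)
  for (i in seq_len(nrow(tree$arcs))) par[[tree$arcs[i, 2]]] <- tree$arcs[i, 1]
  anc <- function(v) {
    out <- v
    while (!is.na(par[[v]])) { v <- par[[v]]; out <- c(out, v) }
    out
  }
  span <- character(0)
  if (length(sel) == 1) span <- sel
  for (i in seq_along(sel)) {
    for (j in seq_along(sel)) {
      if (i >= j) next
      aa <- anc(sel[i]); bb <- anc(sel[j])
      meet <- aa[aa %in% bb][1]
      path <- c(aa[seq_len(match(meet, aa))], rev(bb[seq_len(match(meet, bb) - 1)]))
      span <- union(span, path)
    }
  }
  span_full <- span # node-disjointness is judged on the unsuppressed paths
  arcs <- tree$arcs[tree$arcs[, 1] %in% span & tree$arcs[, 2] %in% span, ,
                    drop = FALSE]
  # suppress degree-2 nodes (indegree 1, outdegree 1 in the induced graph)
  repeat {
    indeg <- table(factor(arcs[, 2], levels = span))
    outdeg <- table(factor(arcs[, 1], levels = span))
    supp <- span[indeg == 1 & outdeg == 1 & !(span %in% names(labels))]
    if (length(supp) == 0) break
    v <- supp[1]
    p <- arcs[arcs[, 2] == v, 1]; c2 <- arcs[arcs[, 1] == v, 2]
    arcs <- arcs[arcs[, 1] != v & arcs[, 2] != v, , drop = FALSE]
    arcs <- rbind(arcs, c(p, c2))
    span <- setdiff(span, v)
  }
  structure(list(arcs = arcs, labels = labels,
                 nodes = if (nrow(arcs) > 0) sort_nodes(unique(c(arcs, names(labels))))
                         else names(labels),
                 span = span_full),
            class = "restricted_tree")
}

restricted_token <- function(rt) {
  canon_token(rt$arcs, rt$nodes, rt$labels, directed = TRUE)
}

#' Agreement forests
#'
#' A partition of `X + {rho}` is an agreement forest for a set of trees on
#' `X` when, for each block, the restrictions of all trees to the block are
#' isomorphic, and for each tree the blocks' path unions are node-disjoint.
#' `maf_size_exhaustive` finds the size (number of blocks) of a maximum
#' agreement forest -- the minimum over all agreement partitions -- by
#' exhausting all partitions (guarded to at most 6 taxa); on two trees this
#' number minus one equals their rSPR distance.
#'
#' @param trees list of reticulation-free `rooted_network`s on the same taxa.
#' @param partition list of character vectors partitioning
#'   `c(taxa, "rho")`.
#' @return `is_agreement_forest`: logical. `maf_size_exhaustive`: integer.
#' @export
is_agreement_forest <- function(trees, partition) {
  taxa <- sort(unname(trees[[1]]$labels))
  got <- sort(unlist(partition))
  if (!identical(got, sort(c(taxa, "rho")))) {
    stop("partition must cover the taxa plus 'rho' exactly once each")
  }
  spans <- vector("list", length(trees))
  for (blk in partition) {
    toks <- character(length(trees))
    for (i in seq_along(trees)) {
      rt <- restrict_tree(trees[[i]], blk)
      toks[i] <- restricted_token(rt)
      spans[[i]] <- c(spans[[i]], list(rt$span))
    }
    if (length(unique(toks)) != 1) return(FALSE)
  }
  for (i in seq_along(trees)) {
    all_nodes <- unlist(spans[[i]])
    if (anyDuplicated(all_nodes)) return(FALSE)
  }
  TRUE
}

#' @rdname is_agreement_forest
#' @param t1,t2 two trees (for `maf_size_exhaustive`).
#' @export
maf_size_exhaustive <- function(t1, t2) {
  taxa <- sort(unname(t1$labels))
  stopifnot(setequal(taxa, unname(t2$labels)))
  if (length(taxa) > 6) stop("size guard: at most 6 taxa")
  items <- c(taxa, "rho")
  best <- Inf
  for (p in set_partitions(items)) {
    if (length(p) >= best) next
    if (is_agreement_forest(list(t1, t2), p)) best <- min(best, length(p))
  }
  as.integer(best)
}

# all partitions of a set, via restricted growth strings
set_partitions <- function(items) {
  n <- length(items)
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      blocks <- split(items, rgs[seq_len(n)])
      out[[length(out) + 1]] <<- unname(blocks)
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1)) {
      rgs[i] <<- v
      recurse(i + 1, max(maxv, v))
    }
  }
  recurse(1, 0)
  out
}

#' Build a mycorrhizal forest
#'
#' Glues tree components onto a root component: the root edge of the i-th
#' tree is identified with the edge leading to the i-th leaf (in sorted
#' label order) of the network `R`. `R` must become biconnected after
#' deleting its root and leaves for the result to be a mycorrhizal forest
#' proper; with a single tree the result is a mycorrhizal tree.
#'
#' @param trees list of `rooted_network` trees with disjoint taxa.
#' @param R a `rooted_network` with `length(trees)` leaves.
#' @return a valid `rooted_network` whose leaves are the union of the trees'
#'   taxa.
#' @export
build_mycorrhizal <- function(trees, R) {
  stopifnot(length(trees) == length(R$labels))
  arcs <- R$arcs
  labels <- character(0)
  slots <- names(R$labels)[order(unname(R$labels))]
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    pre <- paste0("t", i, ".")
    tarcs <- matrix(paste0(pre, tr$arcs), ncol = 2)
    rho_i <- paste0(pre, net_root(tr))
    child <- tarcs[tarcs[, 1] == rho_i, 2]
    tarcs <- tarcs[tarcs[, 1] != rho_i, , drop = FALSE]
    # redirect R's leaf slot to the tree's top node
    slot <- slots[i]
    arcs[arcs[, 2] == slot, 2] <- child
    arcs <- rbind(arcs, tarcs)
    labels <- c(labels, stats::setNames(unname(tr$labels),
                                        paste0(pre, names(tr$labels))))
  }
  rooted_network(arcs, labels)
}

#' treeSPR distance of two mycorrhizal forests with equal root component
#'
#' The sum over tree components of the exact rSPR distances between the
#' corresponding trees, computed with the exhaustive agreement-forest
#' oracle (`maf_size_exhaustive(t, t') - 1` per component).
#'
#' @param treesA,treesB lists of trees, componentwise on the same taxa.
#' @return integer.
#' @export
d_treespr <- function(treesA, treesB) {
  stopifnot(length(treesA) == length(treesB))
  total <- 0L
  for (i in seq_along(treesA)) {
    total <- total + maf_size_exhaustive(treesA[[i]], treesB[[i]]) - 1L
  }
  total
}
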