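#' Canonical form of a network
#'
#' Produces a string token such that two valid rooted networks receive equal
#' tokens if and only if they are isomorphic (arc- and label-preserving,
#' see [is_isomorphic()]). Tokens are stable across runs and are used for
#' deduplication in tier enumeration and breadth-first searches.
#'
#' Backed by BLISS canonical labelling (igraph) on the directed graph with
#' leaves coloured by the rank of their taxon.
#'
#' @param net a valid `rooted_network` (or `unrooted_network`).
#' @return a character scalar.
#' @export
canonical_form <- function(net) {
  UseMethod("canonical_form")
}

#' @export
canonical_form.rooted_network <- function(net) {
  canon_token(net$arcs, net$nodes, net$labels, directed = TRUE)
}

canon_colors <- function(nodes, labels) {
  taxa <- sort(unname(labels))
  cols <- integer(length(nodes))
  names(cols) <- nodes
  cols[names(labels)] <- match(unname(labels), taxa)
  cols
}

# build the igraph object with vertex order = `nodes`
as_igraph_ordered <- function(arcs, nodes, directed) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = directed)
  idx <- stats::setNames(seq_along(nodes), nodes)
  g <- igraph::add_edges(g, rbind(idx[arcs[, 1]], idx[arcs[, 2]]))
  g
}

canon_labeling <- function(arcs, nodes, labels, directed) {
  g <- as_igraph_ordered(arcs, nodes, directed)
  cols <- canon_colors(nodes, labels)
  perm <- igraph::canonical_permutation(g, colors = as.integer(cols))$labeling
  stats::setNames(perm, nodes) # node id -> canonical position
}

canon_token <- function(arcs, nodes, labels, directed) {
  perm <- canon_labeling(arcs, nodes, labels, directed)
  a <- cbind(perm[arcs[, 1]], perm[arcs[, 2]])
  if (!directed) {
    a <- t(apply(a, 1, sort))
  }
  es <- sort(paste0(a[, 1], ">", a[, 2]))
  taxa <- sort(unname(labels))
  labpos <- sort(paste0(perm[names(labels)], "=", labels))
  paste0(if (directed) "D|" else "U|", paste(es, collapse = ";"),
         "|", paste(labpos, collapse = ","))
}

#' Isomorphism between two networks
#'
#' Two rooted networks are isomorphic when a bijection of their nodes
#' preserves arcs (with direction) and maps each labelled leaf to the leaf
#' carrying the same taxon. Returns the mapping when one exists.
#'
#' @param a,b valid `rooted_network` objects.
#' @return a list with `isomorphic` (logical) and, when `TRUE`, `mapping`
#'   (named character vector: node of `a` -> node of `b`).
#' @export
is_isomorphic <- function(a, b) {
  UseMethod("is_isomorphic")
}

#' @export
is_isomorphic.rooted_network <- function(a, b) {
  if (!setequal(unname(a$labels), unname(b$labels))) {
    return(list(isomorphic = FALSE, mapping = NULL))
  }
  iso_by_canon(a$arcs, a$nodes, a$labels, b$arcs, b$nodes, b$labels,
               directed = TRUE)
}

iso_by_canon <- function(arcs_a, nodes_a, labels_a, arcs_b, nodes_b, labels_b,
                         directed) {
  ta <- canon_token(arcs_a, nodes_a, labels_a, directed)
  tb <- canon_token(arcs_b, nodes_b, labels_b, directed)
  if (!identical(ta, tb)) return(list(isomorphic = FALSE, mapping = NULL))
  pa <- canon_labeling(arcs_a, nodes_a, labels_a, directed)
  pb <- canon_labeling(arcs_b, nodes_b, labels_b, directed)
  # map node of a to the node of b at the same canonical position
  inv_b <- stats::setNames(names(pb), pb)
  mapping <- stats::setNames(inv_b[as.character(pa)], names(pa))
  # paranoid verification: arcs must transfer
  key_b <- paste(arcs_b[, 1], arcs_b[, 2])
  if (!directed) {
    key_b <- c(key_b, paste(arcs_b[, 2], arcs_b[, 1]))
  }
  moved <- paste(mapping[arcs_a[, 1]], mapping[arcs_a[, 2]])
  stopifnot(all(moved %in% key_b),
            all(labels_b[mapping[names(labels_a)]] == labels_a))
  list(isomorphic = TRUE, mapping = mapping)
}
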