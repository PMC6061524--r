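#' Unrooted binary phylogenetic network
#'
#' A connected simple graph whose nodes have degree 1 (leaves, labelled
#' bijectively by a taxon set of size >= 2) or degree 3. The reticulation
#' number is k = |E| - |V| + 1.
#'
#' @param edges two-column character matrix of undirected edges.
#' @param labels named character vector, leaf node id -> taxon.
#' @param validate stop on invalid input (default TRUE).
#' @return an object of class `unrooted_network`.
#' @export
unrooted_network <- function(edges, labels, validate = TRUE) {
  edges <- as_arc_matrix(edges)
  edges <- t(apply(edges, 1, function(r) sort_nodes(r)))
  labels <- as_label_vector(labels)
  net <- structure(
    list(nodes = sort_nodes(unique(c(edges, names(labels)))),
         edges = edges, labels = labels),
    class = "unrooted_network")
  if (validate) {
    bad <- validate_unrooted(net)
    if (length(bad) > 0) stop("invalid unrooted network: ",
                              paste(bad, collapse = "; "))
  }
  net
}

#' @export
print.unrooted_network <- function(x, ...) {
  k <- nrow(x$edges) - length(x$nodes) + 1
  cat(sprintf("<unrooted_network: %d leaves, k = %d, %d nodes, %d edges>\n",
              length(x$labels), k, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Validate an unrooted network
#'
#' @param net an `unrooted_network` (possibly built with `validate = FALSE`).
#' @return character vector of violations, empty when valid.
#' @export
validate_unrooted <- function(net) {
  bad <- character(0)
  edges <- net$edges
  if (nrow(edges) == 0) return("no edges")
  key <- paste(edges[, 1], edges[, 2])
  if (anyDuplicated(key)) bad <- c(bad, "parallel edges")
  if (any(edges[, 1] == edges[, 2])) bad <- c(bad, "self-loop")
  deg <- table(factor(c(edges), levels = net$nodes))
  if (!all(deg %in% c(1, 3))) bad <- c(bad, "node degree not in {1, 3}")
  leaves <- net$nodes[deg == 1]
  if (!setequal(names(net$labels), leaves)) {
    bad <- c(bad, "leaf labels must cover exactly the degree-1 nodes")
  }
  if (anyDuplicated(net$labels)) bad <- c(bad, "duplicate taxon labels")
  if (length(net$labels) < 2) bad <- c(bad, "at least two leaves required")
  g <- as_igraph_ordered(edges, net$nodes, directed = FALSE)
  if (igraph::components(g)$no != 1) bad <- c(bad, "not connected")
  bad
}

u_leaves <- function(net) {
  deg <- table(factor(c(net$edges), levels = net$nodes))
  net$nodes[deg == 1]
}

u_neighbors <- function(net, v) {
  c(net$edges[net$edges[, 1] == v, 2], net$edges[net$edges[, 2] == v, 1])
}

u_has_edge <- function(net, a, b) {
  any((net$edges[, 1] == a & net$edges[, 2] == b) |
        (net$edges[, 1] == b & net$edges[, 2] == a))
}

u_tier <- function(net) {
  list(n_leaves = length(net$labels),
       k = nrow(net$edges) - length(net$nodes) + 1,
       n_nodes = length(net$nodes), n_edges = nrow(net$edges))
}

#' @export
canonical_form.unrooted_network <- function(net) {
  canon_token(net$edges, net$nodes, net$labels, directed = FALSE)
}

#' @export
is_isomorphic.unrooted_network <- function(a, b) {
  if (!setequal(unname(a$labels), unname(b$labels))) {
    return(list(isomorphic = FALSE, mapping = NULL))
  }
  iso_by_canon(a$edges, a$nodes, a$labels, b$edges, b$nodes, b$labels,
               directed = FALSE)
}

#' Bridge and blob decomposition
#'
#' `cut_edges` returns the bridges; `blobs` the non-trivial biconnected
#' components (node sets of size >= 3); `redundant_cut_edges` the bridges
#' one of whose sides contains no leaf; `terminal_components` the blobs
#' incident to exactly one cut-edge (each such edge is necessarily
#' redundant).
#'
#' @param net a valid `unrooted_network`.
#' @return `cut_edges`/`redundant_cut_edges`: two-column matrix of edges.
#'   `blobs`: list of character vectors. `terminal_components`: list of
#'   lists with `nodes` and `incident_edges`.
#' @export
cut_edges <- function(net) {
  g <- as_igraph_ordered(net$edges, net$nodes, directed = FALSE)
  br <- igraph::bridges(g)
  if (length(br) == 0) return(matrix(character(0), ncol = 2))
  ends <- igraph::ends(g, br)
  matrix(net$nodes[as.integer(ends)], ncol = 2)
}

#' @rdname cut_edges
#' @export
blobs <- function(net) {
  g <- as_igraph_ordered(net$edges, net$nodes, directed = FALSE)
  bc <- igraph::biconnected_components(g)
  out <- list()
  for (comp in bc$components) {
    ids <- net$nodes[as.integer(comp)]
    if (length(ids) >= 3) out <- c(out, list(sort_nodes(ids)))
  }
  out
}

#' @rdname cut_edges
#' @export
redundant_cut_edges <- function(net) {
  ce <- cut_edges(net)
  leaves <- u_leaves(net)
  keep <- logical(nrow(ce))
  for (i in seq_len(nrow(ce))) {
    sides <- bridge_sides(net, ce[i, ])
    keep[i] <- !any(leaves %in% sides$a) || !any(leaves %in% sides$b)
  }
  ce[keep, , drop = FALSE]
}

bridge_sides <- function(net, e) {
  edges <- net$edges
  drop <- (edges[, 1] == e[1] & edges[, 2] == e[2]) |
    (edges[, 1] == e[2] & edges[, 2] == e[1])
  g <- as_igraph_ordered(edges[!drop, , drop = FALSE], net$nodes,
                         directed = FALSE)
  mem <- igraph::components(g)$membership
  list(a = net$nodes[mem == mem[match(e[1], net$nodes)]],
       b = net$nodes[mem == mem[match(e[2], net$nodes)]])
}

#' @rdname cut_edges
#' @export
terminal_components <- function(net) {
  ce <- cut_edges(net)
  ce_key <- paste(ce[, 1], ce[, 2])
  out <- list()
  for (b in blobs(net)) {
    inc <- net$edges[net$edges[, 1] %in% b | net$edges[, 2] %in% b, ,
                     drop = FALSE]
    inc_cut <- sum(paste(inc[, 1], inc[, 2]) %in% ce_key)
    if (inc_cut == 1) {
      out <- c(out, list(list(nodes = b, incident_edges = inc)))
    }
  }
  out
}

#' Rootability and orientation
#'
#' An unrooted network is rootable iff it has no redundant cut-edge
#' (equivalently, no redundant terminal component). `orient` constructs a
#' rooted network with the chosen leaf as root: cut-edges are directed away
#' from the root leaf and every blob receives a bipolar (acyclic,
#' single-source, single-sink) orientation from its entry node towards a
#' chosen exit node, computed through an open ear decomposition.
#'
#' @param net a valid `unrooted_network`.
#' @param root_leaf a taxon name (or leaf node id) to root at.
#' @return `is_rootable`: logical. `orient`: a `rooted_network` whose
#'   [underlying()] graph equals `net`.
#' @export
is_rootable <- function(net) {
  nrow(redundant_cut_edges(net)) == 0
}

#' @rdname is_rootable
#' @export
orient <- function(net, root_leaf) {
  if (!is_rootable(net)) {
    stop(structure(class = c("not_rootable", "error", "condition"),
                   list(message = "network has a redundant cut-edge",
                        call = sys.call())))
  }
  r <- resolve_leaf(net, root_leaf)
  ce <- cut_edges(net)
  oriented <- matrix(character(0), ncol = 2)
  # direct each cut-edge away from r
  for (i in seq_len(nrow(ce))) {
    sides <- bridge_sides(net, ce[i, ])
    if (r %in% sides$a) oriented <- rbind(oriented, ce[i, ])
    else oriented <- rbind(oriented, rev(ce[i, ]))
  }
  ce_key <- c(paste(ce[, 1], ce[, 2]), paste(ce[, 2], ce[, 1]))
  dir_key <- paste(oriented[, 1], oriented[, 2])
  for (b in blobs(net)) {
    inc_in <- oriented[oriented[, 2] %in% b & !(oriented[, 1] %in% b), ,
                       drop = FALSE]
    inc_out <- oriented[oriented[, 1] %in% b & !(oriented[, 2] %in% b), ,
                        drop = FALSE]
    stopifnot(nrow(inc_in) == 1, nrow(inc_out) >= 1)
    entry <- inc_in[1, 2]
    exit <- least(inc_out[, 1])
    bedges <- net$edges[net$edges[, 1] %in% b & net$edges[, 2] %in% b, ,
                        drop = FALSE]
    bedges <- bedges[!(paste(bedges[, 1], bedges[, 2]) %in% ce_key), ,
                     drop = FALSE]
    ord <- bipolar_order(bedges, b, entry, exit)
    pos <- stats::setNames(seq_along(ord), ord)
    for (i in seq_len(nrow(bedges))) {
      e <- bedges[i, ]
      if (pos[[e[1]]] < pos[[e[2]]]) oriented <- rbind(oriented, e)
      else oriented <- rbind(oriented, rev(e))
    }
  }
  labels <- net$labels[names(net$labels) != r]
  out <- rooted_network(oriented, labels)
  attr(out, "root_label") <- unname(net$labels[[r]])
  out
}

resolve_leaf <- function(net, leaf) {
  if (leaf %in% net$labels) {
    return(names(net$labels)[match(leaf, net$labels)])
  }
  if (leaf %in% names(net$labels)) return(leaf)
  stop("unknown leaf: ", leaf)
}

# st-ordering of a biconnected graph via open ear decomposition: the first
# ear is a cycle through s and t (two internally vertex-disjoint s-t
# paths); each further ear's internal path is inserted as a block directly
# after its earlier endpoint (reversed when needed), so every internal node
# keeps one earlier and one later neighbour. s stays first, t last.
bipolar_order <- function(edges, nodes, s, t) {
  if (length(nodes) == 1) return(nodes)
  paths <- two_disjoint_paths(edges, nodes, s, t)
  ord <- paths[[1]]
  mid2 <- paths[[2]][-c(1, length(paths[[2]]))]
  if (length(mid2) > 0) ord <- append(ord, mid2, after = 1)
  covered_n <- unique(ord)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  covered_e <- character(0)
  mark_path <- function(p) {
    for (i in seq_len(length(p) - 1)) {
      covered_e <<- c(covered_e, ekey(p[i], p[i + 1]))
    }
  }
  mark_path(paths[[1]]); mark_path(paths[[2]])
  all_keys <- ekey(edges[, 1], edges[, 2])
  guard <- 0L
  while (!all(all_keys %in% covered_e)) {
    guard <- guard + 1L
    stopifnot(guard <= nrow(edges) + 1L)
    rem <- edges[!(all_keys %in% covered_e), , drop = FALSE]
    # pick an uncovered edge with a covered endpoint
    i <- which(rem[, 1] %in% covered_n | rem[, 2] %in% covered_n)[1]
    a <- rem[i, 1]; b <- rem[i, 2]
    if (!(a %in% covered_n)) { tmp <- a; a <- b; b <- tmp }
    if (b %in% covered_n) {
      covered_e <- c(covered_e, ekey(a, b)) # chord ear, no internals
      next
    }
    # walk from b through uncovered nodes to a covered node != a
    ear <- ear_path(edges, covered_n, a, b)
    cend <- ear[length(ear)]
    internals <- ear[-length(ear)] # b ... (uncovered)
    pa <- match(a, ord); pc <- match(cend, ord)
    if (pa < pc) {
      ord <- append(ord, internals, after = pa)
    } else {
      ord <- append(ord, rev(internals), after = pc)
    }
    covered_n <- unique(c(covered_n, internals))
    mark_path(c(a, ear))
  }
  stopifnot(ord[1] == s, ord[length(ord)] == t)
  ord
}

ear_path <- function(edges, covered, a, b) {
  # BFS from b over uncovered nodes, stopping at any covered node != a
  prev <- list(); prev[[b]] <- NA_character_
  queue <- b
  nb <- function(v) c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  goal <- NULL
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in nb(v)) {
      if (w == a && v == b) next  # do not walk straight back along the ear edge
      if (!is.null(prev[[w]])) next
      prev[[w]] <- v
      if (w %in% covered) { goal <- w; queue <- list(); break }
      queue <- c(queue, w)
    }
  }
  stopifnot(!is.null(goal))
  path <- goal
  while (path[1] != b) path <- c(prev[[path[1]]], path)
  path
}

# two internally vertex-disjoint s-t paths in a biconnected graph, by
# two rounds of BFS augmentation on the node-split unit-capacity digraph
two_disjoint_paths <- function(edges, nodes, s, t) {
  arcs <- list()
  addarc <- function(u, v) arcs[[length(arcs) + 1]] <<- c(u, v)
  for (v in nodes) {
    if (v != s && v != t) addarc(paste0(v, "/i"), paste0(v, "/o"))
  }
  tag <- function(v, side) {
    if (v == s) paste0(v, "/o") else if (v == t) paste0(v, "/i")
    else paste0(v, "/", side)
  }
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    addarc(tag(u, "o"), tag(v, "i"))
    addarc(tag(v, "o"), tag(u, "i"))
  }
  cap <- new.env(parent = emptyenv())
  for (a in arcs) {
    assign(paste(a[1], a[2]), 1L, envir = cap)
    if (!exists(paste(a[2], a[1]), envir = cap)) {
      assign(paste(a[2], a[1]), 0L, envir = cap)
    }
  }
  vs <- unique(unlist(arcs))
  adj <- stats::setNames(vector("list", length(vs)), vs)
  for (a in arcs) {
    adj[[a[1]]] <- unique(c(adj[[a[1]]], a[2]))
    adj[[a[2]]] <- unique(c(adj[[a[2]]], a[1]))
  }
  src <- paste0(s, "/o"); snk <- paste0(t, "/i")
  for (round in 1:2) {
    # BFS for augmenting path
    prev <- list(); prev[[src]] <- NA_character_
    queue <- src; found <- FALSE
    while (length(queue) > 0 && !found) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!is.null(prev[[w]])) next
        if (get(paste(v, w), envir = cap) < 1L) next
        prev[[w]] <- v
        if (w == snk) { found <- TRUE; break }
        queue <- c(queue, w)
      }
    }
    stopifnot(found)
    w <- snk
    while (w != src) {
      v <- prev[[w]]
      assign(paste(v, w), get(paste(v, w), envir = cap) - 1L, envir = cap)
      assign(paste(w, v), get(paste(w, v), envir = cap) + 1L, envir = cap)
      w <- v
    }
  }
  # extract the two paths by following saturated forward arcs
  used <- new.env(parent = emptyenv())
  out <- list()
  for (round in 1:2) {
    path <- s
    cur <- src
    while (cur != snk) {
      nxt <- NULL
      for (a in arcs) {
        if (a[1] != cur) next
        if (exists(paste("u", a[1], a[2]), envir = used)) next
        if (get(paste(a[1], a[2]), envir = cap) == 0L) { nxt <- a[2]; break }
      }
      stopifnot(!is.null(nxt))
      assign(paste("u", cur, nxt), TRUE, envir = used)
      cur <- nxt
      base <- sub("/[io]$", "", cur)
      if (path[length(path)] != base) path <- c(path, base)
    }
    out <- c(out, list(path))
  }
  out
}

#' Underlying unrooted network of a rooted network
#'
#' Forgets arc directions. The root (outdegree-1, indegree-0) becomes a
#' degree-1 node and is labelled with the rooted network's stored
#' `root_label` attribute when present (as set by [orient()]), otherwise
#' with `"ROOT"`, so `underlying(orient(U, x))` equals `U` exactly.
#'
#' @param net a valid `rooted_network`.
#' @return an `unrooted_network`.
#' @export
underlying <- function(net) {
  rho <- net_root(net)
  rl <- attr(net, "root_label")
  if (is.null(rl)) rl <- "ROOT"
  labels <- c(net$labels, stats::setNames(rl, rho))
  unrooted_network(net$arcs, labels)
}

#' Project a rooted move to an SPR move
#'
#' Every valid rSPR move on a rooted network induces a valid SPR move on
#' its underlying unrooted network: a tail move relocates the tail end of
#' the undirected edge, a head move the head end, and the square of
#' application and projection commutes.
#'
#' @param move a `net_move`.
#' @return an `spr_move`: list with `end` (the relocated node), `edge`
#'   and `target` (unordered node pairs).
#' @export
project_move <- function(move) {
  end <- if (move$kind == "tail") move$edge[1] else move$edge[2]
  structure(list(end = end, edge = move$edge, target = move$target),
            class = "spr_move")
}

#' @export
print.spr_move <- function(x, ...) {
  cat(sprintf("SPR move: %s-end of {%s,%s} -> {%s,%s}\n", x$end,
              x$edge[1], x$edge[2], x$target[1], x$target[2]))
  invisible(x)
}

#' Apply an SPR move to an unrooted network
#'
#' Subdivides the target edge with a new node, removes the moving edge,
#' suppresses the freed degree-2 end and reattaches. Rejected (with an
#' error) when the result is not a valid unrooted network (disconnected or
#' with parallel edges). Tier (|V|, |E|) is conserved. The result carries
#' `"new_node"` and `"inverse"` attributes as for rooted moves.
#'
#' @param net a valid `unrooted_network`.
#' @param end the endpoint of `edge` being relocated.
#' @param edge,target unordered node pairs (length-2 character).
#' @return an `unrooted_network`.
#' @export
apply_spr <- function(net, end, edge, target) {
  stopifnot(end %in% edge)
  if (!u_has_edge(net, edge[1], edge[2])) stop("unknown edge: ",
                                               paste(edge, collapse = ","))
  if (!u_has_edge(net, target[1], target[2])) stop("unknown edge: ",
                                                   paste(target, collapse = ","))
  other <- setdiff(edge, end)
  if (length(other) == 0) other <- end # self pair cannot happen in simple graphs
  edges <- net$edges
  rm1 <- (edges[, 1] == edge[1] & edges[, 2] == edge[2]) |
    (edges[, 1] == edge[2] & edges[, 2] == edge[1])
  rm2 <- (edges[, 1] == target[1] & edges[, 2] == target[2]) |
    (edges[, 1] == target[2] & edges[, 2] == target[1])
  if (all(rm1 == rm2)) stop("edge and target coincide")
  new_id <- fresh_node_id(net)
  edges <- edges[!rm1 & !rm2, , drop = FALSE]
  edges <- rbind(edges, c(target[1], new_id), c(new_id, target[2]))
  nb <- c(edges[edges[, 1] == end, 2], edges[edges[, 2] == end, 1])
  if (length(nb) != 2) stop("invalid SPR move: cannot suppress end of degree ",
                            length(nb))
  edges <- edges[edges[, 1] != end & edges[, 2] != end, , drop = FALSE]
  edges <- rbind(edges, nb, c(new_id, other))
  edges[edges == new_id] <- end # the moved end keeps its id
  nb[nb == new_id] <- end
  cand <- structure(list(nodes = sort_nodes(unique(c(edges))),
                         edges = t(apply(edges, 1, sort_nodes)),
                         labels = net$labels),
                    class = "unrooted_network")
  bad <- validate_unrooted(cand)
  if (length(bad) > 0) stop("invalid SPR move: ", paste(bad, collapse = "; "))
  out <- unrooted_network(cand$edges, cand$labels)
  attr(out, "new_node") <- end
  attr(out, "inverse") <- structure(
    list(end = end, edge = c(end, other), target = nb),
    class = "spr_move")
  out
}

apply_spr_move <- function(net, m) {
  apply_spr(net, m$end, m$edge, m$target)
}

# all valid SPR neighbours (move + result), deduplicated by the caller
enumerate_spr_moves <- function(net) {
  out <- list()
  edges <- net$edges
  for (i in seq_len(nrow(edges))) {
    for (end in edges[i, ]) {
      for (j in seq_len(nrow(edges))) {
        if (i == j) next
        res <- tryCatch(apply_spr(net, end, edges[i, ], edges[j, ]),
                        error = function(e) NULL)
        if (!is.null(res)) {
          out <- c(out, list(list(
            move = structure(list(end = end, edge = edges[i, ],
                                  target = edges[j, ]), class = "spr_move"),
            net = res)))
        }
      }
    }
  }
  out
}

#' Exact SPR distance between unrooted networks
#'
#' Bidirectional BFS over valid SPR moves with canonical deduplication;
#' exact when an integer is returned, `Inf` when the component is
#' exhausted, `NA` when a cap is hit first.
#'
#' @param a,b valid `unrooted_network`s with equal node/edge counts and
#'   taxa.
#' @param cap depth cap.
#' @param node_cap explored-class cap.
#' @return integer, `Inf`, or `NA`.
#' @export
exact_spr_distance <- function(a, b, cap = 6L, node_cap = 20000L) {
  ta <- u_tier(a); tb <- u_tier(b)
  if (!identical(ta, tb) || !setequal(a$labels, b$labels)) {
    stop("tier mismatch")
  }
  ca <- canonical_form(a); cb <- canonical_form(b)
  if (identical(ca, cb)) return(0L)
  fwd <- new.env(parent = emptyenv()); bwd <- new.env(parent = emptyenv())
  assign(ca, a, envir = fwd); assign(cb, b, envir = bwd)
  f_frontier <- list(ca); b_frontier <- list(cb)
  f_depth <- 0L; b_depth <- 0L; n_seen <- 2L
  while (f_depth + b_depth < cap) {
    if (length(f_frontier) == 0 || length(b_frontier) == 0) return(Inf)
    expand_fwd <- length(f_frontier) <= length(b_frontier)
    side <- if (expand_fwd) fwd else bwd
    other <- if (expand_fwd) bwd else fwd
    frontier <- if (expand_fwd) f_frontier else b_frontier
    nxt <- list()
    for (key in frontier) {
      cur <- get(key, envir = side)
      for (nb in enumerate_spr_moves(cur)) {
        ck <- canonical_form(nb$net)
        if (exists(ck, envir = side)) next
        assign(ck, nb$net, envir = side)
        n_seen <- n_seen + 1L
        if (n_seen > node_cap) return(NA_integer_)
        if (exists(ck, envir = other)) return(f_depth + b_depth + 1L)
        nxt <- c(nxt, list(ck))
      }
    }
    if (expand_fwd) { f_frontier <- nxt; f_depth <- f_depth + 1L }
    else { b_frontier <- nxt; b_depth <- b_depth + 1L }
  }
  if (length(f_frontier) == 0 || length(b_frontier) == 0) return(Inf)
  NA_integer_
}

#' Remove one redundant terminal component
#'
#' Applies the constructive SPR move that disarms a redundant terminal
#' component: with cut-edge `{u, v}` (`v` inside the component) and `x, y`
#' the other neighbours of `v`, the `v`-end of `{v, x}` is relocated onto a
#' leaf edge (the canonically least taxon's edge). The result is a valid
#' same-tier network with strictly fewer terminal components, at SPR
#' distance exactly 1.
#'
#' @param net a valid `unrooted_network` with at least one terminal
#'   component.
#' @return list with `net` (the new network) and `move` (the `spr_move`).
#' @export
strip_terminal_component <- function(net) {
  tcs <- terminal_components(net)
  if (length(tcs) == 0) {
    stop(structure(class = c("no_terminal_component", "error", "condition"),
                   list(message = "no redundant terminal component",
                        call = sys.call())))
  }
  firsts <- vapply(tcs, function(z) least(z$nodes), character(1))
  tc <- tcs[[order(nchar(firsts), firsts)[1]]]
  ce <- cut_edges(net)
  inc <- tc$incident_edges
  cut_i <- which(paste(inc[, 1], inc[, 2]) %in% paste(ce[, 1], ce[, 2]))
  stopifnot(length(cut_i) == 1)
  cutedge <- inc[cut_i, ]
  v <- cutedge[cutedge %in% tc$nodes]
  nbrs <- setdiff(u_neighbors(net, v), setdiff(cutedge, v))
  x <- least(nbrs)
  taxa <- sort(unname(net$labels))
  lf <- names(net$labels)[match(taxa[1], net$labels)]
  leaf_edge <- net$edges[net$edges[, 1] == lf | net$edges[, 2] == lf, ]
  res <- apply_spr(net, v, c(v, x), leaf_edge)
  move <- structure(list(end = v, edge = c(v, x), target = leaf_edge),
                    class = "spr_move")
  list(net = res, move = move)
}

#' Make an unrooted network rootable
#'
#' Strips redundant terminal components one by one (at most `floor(k/3)`
#' SPR moves) until the network is rootable.
#'
#' @param net a valid `unrooted_network`.
#' @return list with `net` (rootable) and `moves` (list of `spr_move`).
#' @export
make_rootable <- function(net) {
  moves <- list()
  invs <- list()
  while (length(terminal_components(net)) > 0) {
    st <- strip_terminal_component(net)
    moves <- c(moves, list(st$move))
    invs <- c(invs, list(attr(st$net, "inverse")))
    net <- st$net
  }
  list(net = net, moves = moves, inverses = invs)
}

#' The unrootable five-node fixture
#'
#' The minimal redundant terminal component -- K4 with one edge subdivided,
#' five nodes of degree three within the component and one outgoing
#' cut-edge -- attached to a valid three-leaf remainder. The network has
#' k = 3 and exactly one redundant terminal component, hence is not
#' rootable.
#'
#' @return an `unrooted_network` on taxa `l1, l2, l3`.
#' @export
unrootable_fixture <- function() {
  unrooted_network(rbind(
    c("va", "ka"), c("va", "kb"), c("ka", "kc"), c("ka", "kd"),
    c("kb", "kc"), c("kb", "kd"), c("kc", "kd"),
    c("va", "w"), c("w", "l1"), c("w", "z"), c("z", "l2"), c("z", "l3")),
    c(l1 = "l1", l2 = "l2", l3 = "l3"))
}

#' Enumerate candidate redundant terminal components
#'
#' A redundant terminal component on `m` nodes is a simple connected graph
#' in which one node (the attachment point of the single outgoing cut-edge)
#' has internal degree 2 and every other node has degree 3. This
#' backtracking enumerator counts the labelled graphs with that degree
#' sequence (connectivity checked at the leaves of the search); with
#' `find_only = TRUE` it stops at the first witness. Degree-sum parity
#' makes even `m` impossible, exhaustive search rules out `m = 1, 3`, and
#' the smallest feasible size is `m = 5` -- giving every terminal component
#' an edge excess `|E'| - |V'| = (m + 1)/2 >= 3` (the outgoing cut-edge
#' included in `E'`).
#'
#' @param m number of nodes in the component.
#' @param find_only stop after the first witness.
#' @return number of labelled candidate graphs found (0 or 1 when
#'   `find_only`).
#' @export
terminal_component_candidates <- function(m, find_only = FALSE) {
  degs <- c(2L, rep(3L, m - 1L))
  if (sum(degs) %% 2 == 1) return(0L)
  found <- 0L
  edges <- matrix(integer(0), ncol = 2)
  has <- function(a, b) {
    any((edges[, 1] == a & edges[, 2] == b) |
          (edges[, 1] == b & edges[, 2] == a))
  }
  connected <- function() {
    seen <- logical(m); seen[1] <- TRUE; stack <- 1L
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (i in seq_len(nrow(edges))) {
        w <- if (edges[i, 1] == v) edges[i, 2]
             else if (edges[i, 2] == v) edges[i, 1] else next
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    all(seen)
  }
  recurse <- function() {
    if (find_only && found > 0L) return(invisible(NULL))
    open <- which(degs > 0L)
    if (length(open) == 0L) {
      if (connected()) found <<- found + 1L
      return(invisible(NULL))
    }
    u <- open[1]
    partners <- setdiff(which(degs > 0L), u)
    partners <- partners[!vapply(partners, function(w) has(u, w), logical(1))]
    if (length(partners) < degs[u]) return(invisible(NULL))
    for (comb in utils::combn(partners, degs[u], simplify = FALSE)) {
      saved <- degs; savede <- edges
      for (w in comb) edges <<- rbind(edges, c(u, w))
      degs[comb] <<- degs[comb] - 1L
      degs[u] <<- 0L
      recurse()
      degs <<- saved; edges <<- savede
      if (find_only && found > 0L) return(invisible(NULL))
    }
  }
  recurse()
  found
}

#' SPR sequence connecting two same-tier unrooted networks
#'
#' Connects `U` to `Ut` with at most `n + (8/3) k` SPR moves: both networks
#' are first made rootable (at most `floor(k/3)` strips each), oriented at a
#' common leaf, and the rooted frontier construction is run in `spr` mode,
#' where blocked triangle configurations are resolved by re-orienting the
#' triangle's bottom edge (free at the unrooted level) or by a single
#' target-side tail move. All rooted moves are projected to SPR moves; the
#' emitted sequence acts on `U` only and its replay is verified.
#'
#' @param U,Ut valid `unrooted_network`s with equal node and edge counts
#'   and the same taxa.
#' @return list of `spr_move`s.
#' @export
spr_connect <- function(U, Ut) {
  ta <- u_tier(U); tb <- u_tier(Ut)
  if (!identical(ta, tb) || !setequal(unname(U$labels), unname(Ut$labels))) {
    stop("tier mismatch")
  }
  if (is_isomorphic(U, Ut)$isomorphic) return(list())
  mrA <- make_rootable(U)
  mrB <- make_rootable(Ut)
  r_label <- sort(unname(U$labels))[1]
  NA_ <- orient(mrA$net, r_label)
  NB_ <- orient(mrB$net, r_label)
  build_spr_sequence(U, Ut, mrA, mrB, NA_, NB_)
}

# The actual assembly is done here so that the node-id chains of the
# rooted and unrooted views stay in lockstep (both sides draw fresh ids
# from the same generator over identical node sets).
build_spr_sequence <- function(U, Ut, mrA, mrB, NA_, NB_) {
  seq_spr <- mrA$moves
  Uchain <- mrA$net
  endB <- NB_
  if (!is_isomorphic(NA_, NB_)$isomorphic) {
    state <- init_frontier(NA_, NB_, mode = "spr")
    guard <- 0L
    while (length(state$A$nodes) - length(state$YA) >= 2) {
      state <- extend_frontier(state)
      guard <- guard + 1L
      stopifnot(guard <= 8L * length(state$A$nodes))
    }
    rootA <- net_root(state$A); rootB <- net_root(state$B)
    phi <- c(state$phi, stats::setNames(rootB, rootA))
    fwd <- lapply(state$movesA, `[[`, "move")
    for (m in fwd) {
      pm <- project_move(m)
      Uchain <- apply_spr_move(Uchain, pm)
      seq_spr <- c(seq_spr, list(pm))
    }
    Aend <- state$A
    if (length(state$movesB) > 0) {
      inv_moves <- rev(lapply(state$movesB, `[[`, "inverse"))
      mapBA <- stats::setNames(names(phi), phi)
      tr <- translate_replay(Aend, state$B, mapBA, inv_moves)
      for (m in tr$moves) {
        pm <- project_move(m)
        Uchain <- apply_spr_move(Uchain, pm)
        seq_spr <- c(seq_spr, list(pm))
      }
      endB <- tr$netB
      chi <- tr$map
    } else {
      chi <- stats::setNames(names(phi), phi)
      endB <- state$B
    }
  } else {
    iso <- is_isomorphic(NA_, NB_)
    chi <- stats::setNames(names(iso$mapping), iso$mapping)
    endB <- NB_
  }
  # chi: node of the B rooted chain end (= orientation of stripped Ut,
  # possibly after undoing its frontier moves) -> node of the A chain.
  # Undo the strips of Ut, translated onto the A chain.
  if (length(mrB$inverses) > 0) {
    UB <- underlying_plain(endB, mrB$net)
    invs <- rev(mrB$inverses)
    for (m in invs) {
      tmA <- structure(list(end = unname(chi[[m$end]]),
                            edge = unname(chi[m$edge]),
                            target = unname(chi[m$target])),
                       class = "spr_move")
      resB <- apply_spr_move(UB, m)
      resA <- apply_spr_move(Uchain, tmA)
      chi[attr(resB, "new_node")] <- attr(resA, "new_node")
      UB <- resB
      Uchain <- resA
      seq_spr <- c(seq_spr, list(tmA))
    }
  }
  # verify the whole sequence by replay
  fin <- U
  for (m in seq_spr) fin <- apply_spr_move(fin, m)
  stopifnot(is_isomorphic(fin, Ut)$isomorphic)
  seq_spr
}

# underlying() but keeping the label conventions of the original unrooted
# network `ref`: the rooted root leaf takes the taxon that orient() removed
underlying_plain <- function(net, ref) {
  rho <- net_root(net)
  miss <- setdiff(unname(ref$labels), unname(net$labels))
  stopifnot(length(miss) == 1)
  unrooted_network(net$arcs, c(net$labels, stats::setNames(miss, rho)))
}
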