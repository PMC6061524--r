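# Breadth-first search machinery over move neighbourhoods.
# All searches deduplicate by canonical_form, so they operate on isomorphism
# classes; memory guards return an explicit "gave up" rather than a wrong
# answer.

# all (move, result) neighbours of a network under a move class
neighbor_nets <- function(net, cls) {
  moves <- enumerate_moves(net, cls, nontrivial = FALSE)
  lapply(moves, function(m) list(move = m, net = apply_move(net, m)))
}

#' Shortest tail-move sequence between two networks
#'
#' Bidirectional breadth-first search over valid tail moves with canonical
#' form deduplication, capped at depth `cap`. Returns the shortest sequence
#' (as moves on `a`) whose replay turns `a` into a network isomorphic to
#' `b`, or `NULL` when none exists within the cap.
#'
#' @param a,b valid `rooted_network`s in the same tier with the same labels.
#' @param cap maximum sequence length.
#' @param cls move class searched over (default `"tail"`).
#' @return list of `net_move` (possibly empty), or `NULL` (not found within
#'   cap).
#' @export
tail_reachable <- function(a, b, cap = 4L, cls = "tail") {
  if (!same_tier(a, b)) stop("tier mismatch")
  bidir_path_bfs(a, b, cls, cap)
}

bidir_path_bfs <- function(a, b, cls, cap) {
  ca <- canonical_form(a); cb <- canonical_form(b)
  fwd <- new.env(parent = emptyenv())
  bwd <- new.env(parent = emptyenv())
  assign(ca, list(net = a, path = list()), envir = fwd)
  assign(cb, list(net = b, path = list()), envir = bwd)
  if (identical(ca, cb)) return(combine_paths(a, list(), ca, b, list(), fwd, bwd))
  f_frontier <- list(ca); b_frontier <- list(cb)
  f_depth <- 0L; b_depth <- 0L
  while (f_depth + b_depth < cap &&
         length(f_frontier) > 0 && length(b_frontier) > 0) {
    expand_fwd <- length(f_frontier) <= length(b_frontier)
    side <- if (expand_fwd) fwd else bwd
    other <- if (expand_fwd) bwd else fwd
    frontier <- if (expand_fwd) f_frontier else b_frontier
    nxt <- list()
    hit <- NULL
    for (key in frontier) {
      rec <- get(key, envir = side)
      for (nb in neighbor_nets(rec$net, cls)) {
        ck <- canonical_form(nb$net)
        if (exists(ck, envir = side)) next
        assign(ck, list(net = nb$net, path = c(rec$path, list(nb$move))),
               envir = side)
        nxt <- c(nxt, list(ck))
        if (exists(ck, envir = other)) {
          hit <- ck
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (!is.null(hit)) {
      frec <- get(hit, envir = fwd)
      brec <- get(hit, envir = bwd)
      return(combine_paths(frec$net, frec$path, hit, brec$net, brec$path,
                           fwd, bwd, a))
    }
    if (expand_fwd) {
      f_frontier <- nxt; f_depth <- f_depth + 1L
    } else {
      b_frontier <- nxt; b_depth <- b_depth + 1L
    }
  }
  NULL
}

# forward path reaches fnet; backward path (moves applied from b) reaches
# bnet with canonical(fnet)==canonical(bnet). Emit a single path on `a`.
combine_paths <- function(fnet, fpath, key, bnet, bpath, fwd, bwd, a = NULL) {
  if (length(bpath) == 0) return(fpath)
  # replay backward path from b to collect inverses
  cur <- get(canonical_form_origin(bwd), envir = bwd)$net
  invs <- list()
  for (m in bpath) {
    res <- apply_move(cur, m)
    invs <- c(invs, list(attr(res, "inverse")))
    cur <- res
  }
  # cur is the meet network on the b side; translate inverses onto fnet
  iso <- is_isomorphic(cur, fnet)
  stopifnot(iso$isomorphic)
  tr <- translate_replay(fnet, cur, iso$mapping, rev(invs))
  c(fpath, tr$moves)
}

canonical_form_origin <- function(env) {
  keys <- ls(envir = env)
  for (k in keys) {
    if (length(get(k, envir = env)$path) == 0) return(k)
  }
  stop("origin not found")
}

# Apply `movesB` (valid on netB) to netA in parallel through the node
# mapping mapBA (netB node -> netA node), extending the mapping with each
# pair of created subdivision nodes. Returns the translated moves and the
# final netA.
translate_replay <- function(netA, netB, mapBA, movesB) {
  out <- list()
  for (m in movesB) {
    tm <- net_move(m$kind, unname(mapBA[m$edge]), unname(mapBA[m$target]))
    resB <- apply_move(netB, m)
    resA <- apply_move(netA, tm)
    mapBA[attr(resB, "new_node")] <- attr(resA, "new_node")
    netB <- resB
    netA <- resA
    out <- c(out, list(tm))
  }
  list(moves = out, net = netA, netB = netB, map = mapBA)
}

#' Exact move distance at toy scale
#'
#' Bidirectional BFS over a move class with canonical deduplication.
#' Exact when an answer is returned; `Inf` when the component of `a` is
#' exhausted without meeting `b` (unreachable); `NA` when the depth or node
#' cap was hit first ("gave up", never a wrong answer).
#'
#' @param a,b same-tier networks on the same labels.
#' @param cls move class (see [enumerate_moves()]).
#' @param cap depth cap.
#' @param node_cap explored-class cap.
#' @return integer distance, `Inf`, or `NA`.
#' @export
exact_distance <- function(a, b, cls = "tail", cap = 10L, node_cap = 20000L) {
  if (!same_tier(a, b)) stop("tier mismatch")
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
      for (nb in neighbor_nets(cur, cls)) {
        ck <- canonical_form(nb$net)
        if (exists(ck, envir = side)) next
        assign(ck, nb$net, envir = side)
        n_seen <- n_seen + 1L
        if (n_seen > node_cap) return(NA_integer_)
        if (exists(ck, envir = other)) {
          return(f_depth + b_depth + 1L)
        }
        nxt <- c(nxt, list(ck))
      }
    }
    if (expand_fwd) { f_frontier <- nxt; f_depth <- f_depth + 1L }
    else { b_frontier <- nxt; b_depth <- b_depth + 1L }
  }
  if (length(f_frontier) == 0 || length(b_frontier) == 0) return(Inf)
  NA_integer_
}

# full closure of the isomorphism class of `net` under a move class;
# returns a named list canonical_form -> network (with depth attribute)
move_closure <- function(net, cls, node_cap = 20000L, max_depth = Inf) {
  seen <- new.env(parent = emptyenv())
  ck <- canonical_form(net)
  assign(ck, net, envir = seen)
  frontier <- list(ck)
  depth <- 0L
  n_seen <- 1L
  depths <- stats::setNames(0L, ck)
  while (length(frontier) > 0 && depth < max_depth) {
    nxt <- list()
    for (key in frontier) {
      cur <- get(key, envir = seen)
      for (nb in neighbor_nets(cur, cls)) {
        k2 <- canonical_form(nb$net)
        if (exists(k2, envir = seen)) next
        assign(k2, nb$net, envir = seen)
        n_seen <- n_seen + 1L
        if (n_seen > node_cap) stop("move_closure: node cap exceeded")
        depths[k2] <- depth + 1L
        nxt <- c(nxt, list(k2))
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  keys <- ls(envir = seen)
  out <- stats::setNames(lapply(keys, get, envir = seen), keys)
  attr(out, "depths") <- depths[keys]
  out
}
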