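#' Classify a distance-1 head move
#'
#' Every valid distance-1 head move matches exactly one of six local
#' patterns, determined by which neighbour the moving head `v` shares with
#' the subdivision node: (a) sideways below a tree node (target is the other
#' child edge of `v`'s other parent), (b) sideways above a reticulation
#' (target is the other parent edge of `v`'s reticulation child),
#' (c)/(d) downward through `v`'s tree-node/reticulation child,
#' (e)/(f) upward through `v`'s tree-node/reticulation other parent.
#' Degeneracies among the four surrounding nodes are flagged: `x_eq_y`
#' (cases a, b) and `u_eq_y` (cases d, f) imply the move produces an
#' isomorphic network; `u_eq_w` (case a: the moving tail is the parent of
#' the shared tree node, i.e. a triangle) is the one coinciding-node case
#' with a non-isomorphic result.
#'
#' @param net a valid `rooted_network`.
#' @param move a valid distance-1 head `net_move`.
#' @return list with `case` (one of `"a".."f"`) and logical flags
#'   `x_eq_y`, `u_eq_y`, `u_eq_w`.
#' @export
classify_head1 <- function(net, move) {
  stopifnot(move$kind == "head")
  chk <- check_head_move(net, move$edge, move$target)
  if (!chk$ok) stop("invalid head move (", chk$violation, ")")
  if (move_distance(net, move) != 1L) stop("not a distance-1 head move")
  u <- move$edge[1]; v <- move$edge[2]
  s <- move$target[1]; t <- move$target[2]
  w <- setdiff(net_parents(net, v), u)
  cc <- net_children(net, v)
  x_eq_y <- FALSE; u_eq_y <- FALSE; u_eq_w <- FALSE
  if (s == w) {
    case <- "a"
    x_eq_y <- (t == cc)
    u_eq_w <- identical(net_parents(net, s), u)
  } else if (t == cc) {
    case <- "b"
    x_eq_y <- (s == w)
  } else if (s == cc) {
    case <- if (length(net_parents(net, cc)) == 1) "c" else "d"
    if (case == "d") u_eq_y <- (u %in% setdiff(net_parents(net, cc), v))
  } else if (t == w) {
    case <- if (length(net_parents(net, w)) == 1) "e" else "f"
    if (case == "f") u_eq_y <- (u %in% setdiff(net_parents(net, w), s))
  } else {
    stop("internal: distance-1 head move matches no pattern")
  }
  list(case = case, x_eq_y = x_eq_y, u_eq_y = u_eq_y, u_eq_w = u_eq_w)
}

#' Simulate a distance-1 head move by tail moves
#'
#' Replaces a valid distance-1 head move by a sequence of tail moves whose
#' replay produces a network isomorphic to the head-move result. Moves whose
#' result is isomorphic to the input return the empty sequence. For networks
#' with at least two leaves the sequence has length at most four; the
#' two-leaf tier-1 triangle network is the single exception, where the one
#' nontrivial head move admits no tail simulation at all (an error of class
#' `exceptional_network`). Strategy: the downward-through-a-tree-node case
#' has a one-move constructive shortcut (tail of the tree node's other
#' child edge onto the moving head's other parent edge); all other cases use
#' bounded bidirectional BFS over tail moves, with the cap raised adaptively
#' for one-leaf networks (where no length guarantee is claimed).
#'
#' @param net a valid `rooted_network`.
#' @param move a valid distance-1 head `net_move`.
#' @param cap initial BFS depth cap (default 4, the proven bound).
#' @return list of tail `net_move`s (possibly empty).
#' @export
simulate_head1 <- function(net, move, cap = 4L) {
  cls <- classify_head1(net, move) # validates the move
  target <- apply_head_move(net, move)
  if (identical(canonical_form(target), canonical_form(net))) {
    return(list())
  }
  if (is_exceptional_network(net)) {
    stop(structure(class = c("exceptional_network", "error", "condition"),
                   list(message = paste(
                     "this head move on the two-leaf tier-1 network cannot",
                     "be substituted by tail moves"),
                     call = sys.call())))
  }
  if (cls$case == "c") {
    v <- move$edge[2]
    w <- setdiff(net_parents(net, v), move$edge[1])
    cnode <- net_children(net, v) # the tree node below v
    o <- setdiff(net_children(net, cnode), move$target[2])
    m <- net_move("tail", c(cnode, o), c(w, v))
    if (check_tail_move(net, m$edge, m$target)$ok) {
      res <- apply_tail_move(net, m)
      if (is_isomorphic(res, target)$isomorphic) return(list(m))
    }
    # fall through to BFS on (unexpected) degeneracies
  }
  caps <- if (length(net$labels) == 1) c(cap, 6L, 8L) else cap
  for (cp in caps) {
    seq <- tail_reachable(net, target, cap = cp)
    if (!is.null(seq)) {
      return(verify_simulation(net, seq, target))
    }
  }
  stop("no tail-move simulation found within cap ", max(caps),
       " (|X| = ", length(net$labels), ")")
}

verify_simulation <- function(net, moves, target) {
  cur <- net
  for (m in moves) {
    stopifnot(m$kind == "tail")
    cur <- apply_tail_move(cur, m)
  }
  stopifnot(is_isomorphic(cur, target)$isomorphic)
  moves
}

#' Replay a move sequence
#'
#' Applies moves in order, stopping with an error if any prefix is invalid.
#'
#' @param net a valid `rooted_network`.
#' @param moves list of `net_move`.
#' @return the final `rooted_network`.
#' @export
replay_moves <- function(net, moves) {
  for (m in moves) net <- apply_move(net, m)
  net
}
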