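# Constructive same-tier connectivity: the frontier algorithm.
#
# The engine grows downward-closed node sets Y (in the evolving copy A of
# the source network) and Y' (in the copy B of the target) together with an
# isomorphism phi between the induced subgraphs, starting from the leaves.
# Each extension step adds one node pair at a bounded move cost:
#   - tail mode: <= 3 tail moves per node (so <= 3(n+2k) in total);
#   - rspr mode: <= 1 head move per reticulation, <= 2 moves per tree node
#     (so <= 2n+3k-1 in total);
#   - spr mode (used by the unrooted connector): <= 1 move per node, using
#     free re-orientations of triangle bottom edges in the rooted view.
# Moves performed on the target side are recorded with their inverses and
# emitted reversed at the end, translated onto the source chain through the
# final isomorphism, so the emitted sequence acts on the source only.

#' Initialise a frontier state
#'
#' Sets up the connectivity construction between two same-tier networks on
#' the same taxa: `Y` and `Y'` start as the leaf sets, matched by label.
#'
#' @param N source network.
#' @param Nt target network.
#' @param mode `"tail"`, `"rspr"` or `"spr"` (see [tail_connect()],
#'   [rspr_connect()]).
#' @return an object of class `frontier_state`.
#' @export
init_frontier <- function(N, Nt, mode = c("tail", "rspr", "spr")) {
  mode <- match.arg(mode)
  if (!same_tier(N, Nt)) stop("tier mismatch")
  if (mode == "tail" &&
      (is_exceptional_network(N) || is_exceptional_network(Nt))) {
    stop(structure(class = c("excluded_instance", "error", "condition"),
                   list(message = paste(
                     "tail-move connectivity excludes the exceptional",
                     "networks (k = 1 with two leaves, k = 2 with one leaf)"),
                     call = sys.call())))
  }
  la <- net_leaves(N); lb <- net_leaves(Nt)
  phi <- stats::setNames(
    names(Nt$labels)[match(N$labels[la], Nt$labels)], la)
  structure(list(A = N, B = Nt, YA = la, YB = lb, phi = phi,
                 movesA = list(), movesB = list(), mode = mode),
            class = "frontier_state")
}

#' @export
print.frontier_state <- function(x, ...) {
  cat(sprintf("<frontier_state: |Y| = %d of %d, %d+%d moves emitted>\n",
              length(x$YA), length(x$A$nodes), length(x$movesA),
              length(x$movesB)))
  invisible(x)
}

lowest_nodes <- function(net, Y) {
  comp <- setdiff(net$nodes, Y)
  low <- comp[vapply(comp, function(v) all(net_children(net, v) %in% Y),
                     logical(1))]
  sort_nodes(low)
}

least <- function(ids) sort_nodes(ids)[1]

#' Extend a frontier state by one node pair
#'
#' Performs one step of the case analysis of the connectivity construction,
#' strictly decreasing the complement of `Y` (except for the move-free
#' triangle re-orientation of `spr` mode, which is immediately followed by a
#' decreasing step). Returns the updated state; the moves just emitted are
#' in `attr(state, "last_moves")`.
#'
#' @param state a `frontier_state` with `|V(A)| - |Y| >= 2`.
#' @return the updated `frontier_state`.
#' @export
extend_frontier <- function(state) {
  sz <- length(state$A$nodes) - length(state$YA)
  stopifnot(sz >= 2)
  lowB <- lowest_nodes(state$B, state$YB)
  lowA <- lowest_nodes(state$A, state$YA)
  retB <- lowB[vapply(lowB, function(v)
    length(net_parents(state$B, v)) == 2, logical(1))]
  retA <- lowA[vapply(lowA, function(v)
    length(net_parents(state$A, v)) == 2, logical(1))]
  inv_phi <- stats::setNames(names(state$phi), state$phi)
  if (length(retB) > 0) {
    res <- frontier_case1(state$A, state$B, state$YA, state$YB, inv_phi,
                          state$mode, least(retB))
    state$A <- res$A; state$YA <- res$YA; state$YB <- res$YB
    state$phi <- stats::setNames(names(res$mapBA), unname(res$mapBA))
    state$movesA <- c(state$movesA, res$moves)
    attr(state, "last_moves") <- lapply(res$moves, `[[`, "move")
  } else if (length(retA) > 0) {
    res <- frontier_case1(state$B, state$A, state$YB, state$YA, state$phi,
                          state$mode, least(retA))
    state$B <- res$A; state$YB <- res$YA; state$YA <- res$YB
    state$phi <- stats::setNames(unname(res$mapBA), names(res$mapBA))
    state$movesB <- c(state$movesB, res$moves)
    attr(state, "last_moves") <- lapply(res$moves, `[[`, "move")
  } else {
    res <- frontier_case3(state)
    state <- res$state
    attr(state, "last_moves") <- res$last_moves
  }
  state
}

# Case 1 (and, with swapped arguments, Case 2): a lowest node u_p of B \ YB
# is a reticulation. Prepare A (with at most 3 tail moves, or 1 head move in
# rspr/spr mode) until the A-image x of u_p's child has a reticulation
# parent z outside YA, then add the pair z <-> u_p.
# mapBA maps B nodes to A nodes; moves are returned as
# list(move =, inverse =) pairs acting on A.
frontier_case1 <- function(A, B, YA, YB, mapBA, mode, u_p) {
  x_p <- net_children(B, u_p)
  stopifnot(length(x_p) == 1, x_p %in% YB)
  x <- unname(mapBA[[x_p]])
  moves <- list()
  push <- function(m, res) {
    moves[[length(moves) + 1]] <<- list(move = m, inverse = attr(res, "inverse"))
  }
  guard <- 0L
  repeat {
    guard <- guard + 1L
    stopifnot(guard <= 4L)
    pars <- setdiff(net_parents(A, x), YA)
    stopifnot(length(pars) >= 1)
    retp <- pars[vapply(pars, function(p)
      length(net_parents(A, p)) == 2, logical(1))]
    if (length(retp) > 0) { z <- least(retp); break }
    z <- least(pars) # a tree node
    if (mode %in% c("rspr", "spr")) {
      done <- FALSE
      retics <- sort_nodes(setdiff(net_reticulations(A), YA))
      stopifnot(length(retics) > 0)
      for (v in retics) {
        for (q in sort_nodes(net_parents(A, v))) {
          m <- net_move("head", c(q, v), c(z, x))
          if (check_head_move(A, m$edge, m$target)$ok) {
            res <- apply_head_move(A, m)
            push(m, res); A <- res
            done <- TRUE; break
          }
        }
        if (done) break
      }
      stopifnot(done) # the construction guarantees a valid head move
      next
    }
    mv <- is_movable(A, c(z, x))
    if (mv$movable) {
      u <- least(setdiff(net_reticulations(A), YA))
      v <- net_children(A, u)
      stopifnot(v != x) # x would then have had a reticulation parent
      if (z != v) {
        m1 <- net_move("tail", c(z, x), c(u, v))
        res <- apply_tail_move(A, m1); push(m1, res); A <- res
        znode <- attr(res, "new_node")
      } else {
        znode <- z
      }
      oth <- setdiff(net_children(A, znode), x)
      w <- least(net_parents(A, u))
      m2 <- net_move("tail", c(znode, oth), c(w, u))
      res <- apply_tail_move(A, m2); push(m2, res); A <- res
      # u is now the reticulation parent of x
      next
    }
    # (z, x) blocked by a triangle c, z, d with long edge (c, d)
    cc <- net_parents(A, z)
    d <- setdiff(net_children(A, z), x)
    stopifnot(has_arc(A, cc, d))
    b <- net_parents(A, cc)
    if (length(net_parents(A, b)) > 0) {
      a <- least(net_parents(A, b))
      m0 <- net_move("tail", c(cc, d), c(a, b))
      res <- apply_tail_move(A, m0); push(m0, res); A <- res
      next # (z, x) is movable now
    }
    # b is the root: the "swap" of Case 1(b)iiB
    sw <- case_b_swap(A, cc, z, d, x, YA, mapBA, push)
    A <- sw$A; x <- sw$x; YA <- sw$YA; mapBA <- sw$mapBA
  }
  YA <- c(YA, z); YB <- c(YB, u_p)
  mapBA[[u_p]] <- z
  list(A = A, YA = YA, YB = YB, mapBA = mapBA, moves = moves)
}

# The root-triangle swap: equivalent to moving the head of the long edge
# (c, d) onto (z, x), realised as three tail moves that interchange the
# subtrees hanging at x (below the tree node z) and at e (below the
# reticulation d). Falls back to a cap-3 BFS plus isomorphism
# reconciliation on degenerate leaf/reticulation coincidences.
case_b_swap <- function(A, cc, z, d, x, YA, mapBA, push) {
  stopifnot(!(d %in% YA))
  e <- net_children(A, d)
  x_tree <- length(net_children(A, x)) == 2
  e_tree <- length(net_children(A, e)) == 2
  if (x_tree) {
    for (kids in child_orders(A, x)) {
      s <- kids[1]; t <- kids[2]
      st <- run_swap_steps(A, list(
        function(A1, ids) net_move("tail", c(x, s), c(d, e)),
        function(A1, ids) net_move("tail", c(ids[1], e), c(z, t)),
        function(A1, ids) net_move("tail", c(ids[2], t), c(d, s))
      ), push_probe = TRUE)
      if (!is.null(st)) {
        # x was suppressed; its replacement is the third new node
        x_new <- st$ids[3]
        for (p in st$done) push(p$move, p$res)
        YA[YA == x] <- x_new
        mapBA[mapBA == x] <- x_new
        return(list(A = st$A, x = x_new, YA = YA, mapBA = mapBA))
      }
    }
  }
  if (e_tree) {
    for (kids in child_orders(A, e)) {
      s <- kids[1]; t <- kids[2]
      st <- run_swap_steps(A, list(
        function(A1, ids) net_move("tail", c(e, s), c(z, x)),
        function(A1, ids) net_move("tail", c(ids[1], x), c(d, t)),
        function(A1, ids) net_move("tail", c(ids[2], t), c(z, s))
      ), push_probe = TRUE)
      if (!is.null(st)) {
        e_new <- st$ids[3]
        for (p in st$done) push(p$move, p$res)
        if (e %in% YA) {
          YA[YA == e] <- e_new
          mapBA[mapBA == e] <- e_new
        }
        return(list(A = st$A, x = x, YA = YA, mapBA = mapBA))
      }
    }
  }
  # degenerate corner: find any 3-tail-move realisation of the head move
  target <- apply_head_move(A, net_move("head", c(cc, d), c(z, x)))
  seqm <- tail_reachable(A, target, cap = 3L)
  if (is.null(seqm)) stop("internal: case B swap found no 3-move sequence")
  cur <- A
  for (m in seqm) {
    res <- apply_tail_move(cur, m)
    push(m, res)
    cur <- res
  }
  iso <- is_isomorphic(cur, target)
  stopifnot(iso$isomorphic)
  # target retains the ids of YA (only d, outside YA, was suppressed);
  # re-express YA and the mapping in the id space of cur
  inv <- stats::setNames(names(iso$mapping), iso$mapping) # target -> cur
  YA2 <- unname(inv[YA])
  stopifnot(!anyNA(YA2))
  mapBA2 <- stats::setNames(unname(inv[mapBA]), names(mapBA))
  stopifnot(!anyNA(mapBA2))
  list(A = cur, x = unname(inv[[x]]), YA = YA2, mapBA = mapBA2)
}

child_orders <- function(net, v) {
  kids <- sort_nodes(net_children(net, v))
  list(kids, rev(kids))
}

# run the three closure-generated moves, validating each; returns NULL when
# any step is invalid
run_swap_steps <- function(A, steps, push_probe = FALSE) {
  cur <- A
  ids <- character(0)
  done <- list()
  for (f in steps) {
    m <- f(cur, ids)
    if (!all(c(has_arc(cur, m$edge[1], m$edge[2]),
               has_arc(cur, m$target[1], m$target[2])))) return(NULL)
    if (!check_tail_move(cur, m$edge, m$target)$ok) return(NULL)
    res <- apply_tail_move(cur, m)
    ids <- c(ids, attr(res, "new_node"))
    done <- c(done, list(list(move = m, res = res)))
    cur <- res
  }
  list(A = cur, ids = ids, done = done)
}

# Case 3: every lowest node on both sides is a tree node.
frontier_case3 <- function(state) {
  A <- state$A; B <- state$B; YA <- state$YA; YB <- state$YB
  inv_phi <- stats::setNames(names(state$phi), state$phi)
  lowB <- lowest_nodes(B, YB)
  u_p <- least(lowB)
  kids_p <- sort_nodes(net_children(B, u_p))
  x_p <- kids_p[1]; y_p <- kids_p[2]
  x <- unname(inv_phi[[x_p]]); y <- unname(inv_phi[[y_p]])
  movesA <- list(); movesB <- list()
  pushA <- function(m, res) movesA[[length(movesA) + 1]] <<-
    list(move = m, inverse = attr(res, "inverse"))
  pushB <- function(m, res) movesB[[length(movesB) + 1]] <<-
    list(move = m, inverse = attr(res, "inverse"))
  common <- setdiff(intersect(net_parents(A, x), net_parents(A, y)), YA)
  added <- NULL
  if (length(common) > 0) {
    added <- least(common) # Case 3a: zero moves
  } else {
    zx <- least(setdiff(net_parents(A, x), YA))
    zy <- least(setdiff(net_parents(A, y), YA))
    mvx <- is_movable(A, c(zx, x))
    mvy <- is_movable(A, c(zy, y))
    if (mvx$movable || mvy$movable) {
      if (!mvx$movable) { tmp <- x; x <- y; y <- tmp
                          tmp <- zx; zx <- zy; zy <- tmp }
      m <- net_move("tail", c(zx, x), c(zy, y))
      stopifnot(check_tail_move(A, m$edge, m$target)$ok)
      res <- apply_tail_move(A, m); pushA(m, res); A <- res
      added <- attr(res, "new_node")
    } else {
      # Case 3(b)iii: both incoming edges blocked by triangles
      dx <- setdiff(net_children(A, zx), x)
      dy <- setdiff(net_children(A, zy), y)
      if (state$mode == "spr" && !(dy %in% YA)) {
        state$A <- flip_arc(A, zy, dy)
        attr(state, "last_moves") <- list()
        return(list(state = state, last_moves = list()))
      }
      if (state$mode == "spr" && !(dx %in% YA)) {
        state$A <- flip_arc(A, zx, dx)
        attr(state, "last_moves") <- list()
        return(list(state = state, last_moves = list()))
      }
      if (state$mode == "spr") {
        # dx, dy both in YA: one tail move on the target side (Fig 21)
        res3 <- spr_case3_target_move(B, YB, state$phi, u_p, x_p, y_p,
                                      dx, dy, zx, zy)
        pushB(res3$move, res3$res)
        B <- res3$B
        state$B <- B
        state$YA <- c(YA, res3$zA)
        state$YB <- c(YB, res3$nn)
        state$phi[res3$zA] <- res3$nn
        state$movesB <- c(state$movesB, movesB)
        lm <- lapply(movesB, `[[`, "move")
        attr(state, "last_moves") <- lm
        return(list(state = state, last_moves = lm))
      }
      cx <- net_parents(A, zx)
      cy <- net_parents(A, zy)
      stopifnot(cx != cy)
      root <- net_root(A)
      # lift on whichever side's triangle top is not the child of the root
      if (net_parents(A, cx) == root) {
        tmp <- x; x <- y; y <- tmp
        tmp <- zx; zx <- zy; zy <- tmp
        tmp <- dx; dx <- dy; dy <- tmp
        tmp <- cx; cx <- cy; cy <- tmp
      }
      bx <- net_parents(A, cx)
      ax <- least(net_parents(A, bx))
      m0 <- net_move("tail", c(cx, dx), c(ax, bx))
      stopifnot(check_tail_move(A, m0$edge, m0$target)$ok)
      res <- apply_tail_move(A, m0); pushA(m0, res); A <- res
      m <- net_move("tail", c(zx, x), c(zy, y))
      stopifnot(check_tail_move(A, m$edge, m$target)$ok)
      res <- apply_tail_move(A, m); pushA(m, res); A <- res
      added <- attr(res, "new_node")
    }
  }
  state$A <- A
  state$YA <- c(YA, added)
  state$YB <- c(YB, u_p)
  state$phi[added] <- u_p
  state$movesA <- c(state$movesA, movesA)
  lm <- lapply(movesA, `[[`, "move")
  attr(state, "last_moves") <- lm
  list(state = state, last_moves = lm)
}

flip_arc <- function(net, from, to) {
  arcs <- net$arcs
  i <- which(arcs[, 1] == from & arcs[, 2] == to)
  stopifnot(length(i) == 1)
  arcs[i, ] <- c(to, from)
  rooted_network(arcs, net$labels)
}

# Fig 21 move: tail-move (u_p, x_p) in the target-side network onto an
# incoming edge of the image of dx, so that x_p and that image share a new
# lowest tree-node parent; performed on whichever of the x / y sides admits
# a valid move.
spr_case3_target_move <- function(B, YB, phi, u_p, x_p, y_p, dx, dy, zx, zy) {
  cands <- list(list(leafside = x_p, d = dx, z = zx),
                list(leafside = y_p, d = dy, z = zy))
  for (cd in cands) {
    d_img <- unname(phi[[cd$d]])
    for (q in sort_nodes(net_parents(B, d_img))) {
      m <- net_move("tail", c(u_p, cd$leafside), c(q, d_img))
      if (!check_tail_move(B, m$edge, m$target)$ok) next
      res <- apply_tail_move(B, m)
      nn <- attr(res, "new_node")
      return(list(B = res, move = m, res = res, nn = nn, zA = cd$z))
    }
  }
  stop("internal: no valid target-side move in spr case 3(b)iii")
}

#' Tail-move sequence connecting two same-tier networks
#'
#' Constructs a sequence of at most `3(n + 2k)` tail moves turning `N` into
#' a network isomorphic to `Nt` (same tier, same taxa), by the frontier
#' construction. Every prefix of the returned sequence is a valid network
#' of constant tier. The exceptional networks (two leaves with k = 1, one
#' leaf with k = 2) are refused with an error of class `excluded_instance`;
#' use [rspr_connect()] there.
#'
#' @param N,Nt valid `rooted_network`s in the same tier on the same taxa.
#' @return list of tail `net_move`s acting on `N`.
#' @export
tail_connect <- function(N, Nt) {
  connect_engine(N, Nt, "tail")
}

#' rSPR (head + tail) sequence connecting two same-tier networks
#'
#' As [tail_connect()] but allowing head moves, which shortens the
#' construction to at most `2n + 3k - 1` moves and removes the tier
#' exclusions: every pair of same-tier networks is connected under rSPR.
#'
#' @inheritParams tail_connect
#' @return list of `net_move`s acting on `N`.
#' @export
rspr_connect <- function(N, Nt) {
  connect_engine(N, Nt, "rspr")
}

connect_engine <- function(N, Nt, mode) {
  if (!same_tier(N, Nt)) stop("tier mismatch")
  if (is_isomorphic(N, Nt)$isomorphic) return(list())
  state <- init_frontier(N, Nt, mode)
  guard <- 0L
  while (length(state$A$nodes) - length(state$YA) >= 2) {
    state <- extend_frontier(state)
    guard <- guard + 1L
    stopifnot(guard <= 8L * length(state$A$nodes))
  }
  emit_frontier_moves(N, Nt, state)
}

# finalize: map root to root, translate target-side inverses onto the
# source chain, verify the replay
emit_frontier_moves <- function(N, Nt, state) {
  rootA <- net_root(state$A); rootB <- net_root(state$B)
  phi <- c(state$phi, stats::setNames(rootB, rootA))
  stopifnot(length(phi) == length(state$A$nodes))
  fwd <- lapply(state$movesA, `[[`, "move")
  out <- fwd
  if (length(state$movesB) > 0) {
    inv_moves <- rev(lapply(state$movesB, `[[`, "inverse"))
    mapBA <- stats::setNames(names(phi), phi) # B-final node -> A-final node
    tr <- translate_replay(state$A, state$B, mapBA, inv_moves)
    out <- c(fwd, tr$moves)
  }
  final <- replay_moves(N, out)
  stopifnot(is_isomorphic(final, Nt)$isomorphic)
  out
}

#' Decompose a tail move into distance-1 tail moves
#'
#' Replaces one valid tail move of `(u,v)` to `(s,t)` by a sequence of at
#' most `n + 3k - 1` distance-1 tail moves with the same composite result:
#' the tail slides along a directed path from `u` up to a lowest common
#' ancestor of `u` and `s`, then down to `s`, one edge at a time.
#'
#' @param net a valid `rooted_network`.
#' @param move a valid tail `net_move`.
#' @return list of distance-1 tail `net_move`s; replaying them yields a
#'   network isomorphic to `apply_tail_move(net, move)`.
#' @export
decompose_tail_move <- function(net, move) {
  stopifnot(move$kind == "tail")
  chk <- check_tail_move(net, move$edge, move$target)
  if (!chk$ok) stop("invalid tail move (", chk$violation, ")")
  u <- move$edge[1]; v <- move$edge[2]
  s <- move$target[1]; t <- move$target[2]
  direct <- apply_tail_move(net, move)
  l <- least(lca_set(net, u, s))
  up <- shortest_directed_path(net, l, u)   # nodes l .. u
  down <- shortest_directed_path(net, l, s) # nodes l .. s
  # targets: edges up the path from u (excluding u's own parent edge),
  # then down the path, then the final target
  targets <- list()
  if (length(up) >= 3) {
    for (i in seq(length(up) - 1, 2)) {
      targets <- c(targets, list(c(up[i - 1], up[i])))
    }
  }
  if (length(down) >= 2) {
    for (i in seq(2, length(down))) {
      targets <- c(targets, list(c(down[i - 1], down[i])))
    }
  }
  # when s is the chosen LCA itself, f already occurs among the path
  # targets; the hop onto it is then the final move
  hit <- which(vapply(targets, function(tg) tg[1] == s && tg[2] == t,
                      logical(1)))
  if (length(hit) > 0) {
    targets <- targets[seq_len(hit[1])]
  } else {
    targets <- c(targets, list(c(s, t)))
  }
  cur <- net
  moving <- c(u, v)
  out <- list()
  for (tg in targets) {
    if (identical(unname(tg), unname(moving)) ||
        (tg[1] == moving[1] && tg[2] == moving[2])) next
    m <- net_move("tail", moving, tg)
    if (!check_tail_move(cur, m$edge, m$target)$ok) {
      stop("internal: invalid hop in decomposition: ", format(m))
    }
    d <- move_distance(cur, m)
    if (d == 0L) { # trivial hop onto the adjacent edge; skip it
      next
    }
    stopifnot(d == 1L)
    res <- apply_tail_move(cur, m)
    moving <- c(attr(res, "new_node"), v)
    cur <- res
    out <- c(out, list(m))
  }
  stopifnot(is_isomorphic(cur, direct)$isomorphic)
  out
}

shortest_directed_path <- function(net, from, to) {
  if (from == to) return(from)
  ch <- split(net$arcs[, 2], factor(net$arcs[, 1], levels = net$nodes))
  prev <- stats::setNames(rep(NA_character_, length(net$nodes)), net$nodes)
  seen <- stats::setNames(logical(length(net$nodes)), net$nodes)
  queue <- from; seen[[from]] <- TRUE
  while (length(queue) > 0) {
    vtx <- queue[[1]]; queue <- queue[-1]
    if (vtx == to) break
    for (w in ch[[vtx]]) {
      if (!seen[[w]]) {
        seen[[w]] <- TRUE; prev[[w]] <- vtx; queue <- c(queue, w)
      }
    }
  }
  stopifnot(seen[[to]])
  path <- to
  while (path[1] != from) path <- c(prev[[path[1]]], path)
  path
}
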