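#' Enumerate a tier up to isomorphism
#'
#' Returns one representative per isomorphism class of the tier (n, k) on
#' labels `x1..xn` (or the supplied labels). The primary enumerator is
#' breadth-first closure under rSPR (head + tail) moves from a single
#' deterministic representative, which is exhaustive because every tier is
#' connected under rNNI moves (a subset of rSPR). An independent
#' constructive enumerator ([enumerate_tier_constructive()]) cross-checks
#' it in the test suite.
#'
#' @param n number of leaves (>= 1).
#' @param k reticulation number (>= 0).
#' @param labels optional taxon labels, length `n`.
#' @param max_nodes guard: refuse when 2n + 2k exceeds this (default 10).
#' @param node_cap BFS memory guard.
#' @return named list canonical_form -> `rooted_network`.
#' @export
enumerate_tier <- function(n, k, labels = NULL, max_nodes = 10L,
                           node_cap = 50000L) {
  if (2 * n + 2 * k > max_nodes) {
    stop("size guard exceeded: 2n+2k = ", 2 * n + 2 * k, " > ", max_nodes)
  }
  rep <- representative_network(n, k, labels)
  if (is.null(rep)) return(list())  # empty tier
  move_closure(rep, "rspr", node_cap = node_cap)
}

#' @rdname enumerate_tier
#' @export
enumerate_tier_constructive <- function(n, k, labels = NULL, max_nodes = 10L) {
  if (2 * n + 2 * k > max_nodes) {
    stop("size guard exceeded: 2n+2k = ", 2 * n + 2 * k, " > ", max_nodes)
  }
  cur <- all_trees(n, labels)
  for (i in seq_len(k)) {
    nxt <- list()
    for (net in cur) {
      arcs <- net$arcs
      for (a1 in seq_len(nrow(arcs))) {
        for (a2 in seq_len(nrow(arcs))) {
          if (a1 == a2) next
          res <- add_reticulation(net, arcs[a1, ], arcs[a2, ])
          if (is.null(res)) next
          ck <- canonical_form(res)
          if (is.null(nxt[[ck]])) nxt[[ck]] <- res
        }
      }
    }
    cur <- nxt
  }
  cur
}

# subdivide e1 with the new tail, e2 with the new head, connect; NULL when
# the result is not a valid network
add_reticulation <- function(net, e1, e2) {
  ids <- fresh_node_id(net, 2)
  a <- ids[1]; b <- ids[2]
  arcs <- net$arcs
  arcs <- arcs[!(arcs[, 1] == e1[1] & arcs[, 2] == e1[2]), , drop = FALSE]
  arcs <- rbind(arcs, c(e1[1], a), c(a, e1[2]))
  arcs <- arcs[!(arcs[, 1] == e2[1] & arcs[, 2] == e2[2]), , drop = FALSE]
  arcs <- rbind(arcs, c(e2[1], b), c(b, e2[2]))
  arcs <- rbind(arcs, c(a, b))
  cand <- structure(list(nodes = sort_nodes(unique(c(arcs))), arcs = arcs,
                         labels = net$labels), class = "rooted_network")
  if (length(validate_rooted(cand)) > 0) return(NULL)
  rooted_network(arcs, net$labels)
}

# all rooted binary trees on the labels, by recursive leaf insertion
all_trees <- function(n, labels = NULL) {
  labels <- default_labels(n, labels)
  base <- rooted_network(rbind(c("r", "v1"), c("v1", "L1"), c("v1", "L2")),
                         stats::setNames(labels[1:2], c("L1", "L2")))
  if (n == 1) {
    return(stats::setNames(list(
      rooted_network(rbind(c("r", "L1")), stats::setNames(labels[1], "L1"))
    ), "tree1"))
  }
  cur <- list(base)
  for (i in seq_len(n - 2) + 2) {
    nxt <- list()
    for (net in cur) {
      leaf_id <- paste0("L", i)
      for (j in seq_len(nrow(net$arcs))) {
        e <- net$arcs[j, ]
        mid <- fresh_node_id(net)
        arcs <- net$arcs[-j, , drop = FALSE]
        arcs <- rbind(arcs, c(e[1], mid), c(mid, e[2]), c(mid, leaf_id))
        labs <- c(net$labels, stats::setNames(labels[i], leaf_id))
        nxt <- c(nxt, list(rooted_network(arcs, labs)))
      }
    }
    cur <- nxt
  }
  out <- list()
  for (net in cur) {
    ck <- canonical_form(net)
    if (is.null(out[[ck]])) out[[ck]] <- net
  }
  out
}

default_labels <- function(n, labels = NULL) {
  if (is.null(labels)) labels <- paste0("x", seq_len(n))
  stopifnot(length(labels) == n)
  labels
}

# deterministic representative of tier (n, k): caterpillar tree plus k
# reticulations added greedily in canonical arc order. Tier (1, 1) is empty
# (a single reticulation on one leaf cannot find two distinct parents), and
# no (1, 2) network arises by adding one reticulation to a smaller network,
# so the one-leaf tiers start from the hand-built tier-(1, 2) fixture.
representative_network <- function(n, k, labels = NULL) {
  labels <- default_labels(n, labels)
  if (n == 1 && k == 1) return(NULL)
  if (n == 1 && k >= 2) {
    net <- fixtures("exceptional_one_leaf")
    net$labels[] <- labels
    k <- k - 2L
  } else {
    net <- caterpillar_tree(labels)
  }
  for (i in seq_len(k)) {
    arcs <- net$arcs
    ord <- order(match(arcs[, 1], net$nodes), match(arcs[, 2], net$nodes))
    arcs <- arcs[ord, , drop = FALSE]
    done <- FALSE
    for (a1 in seq_len(nrow(arcs))) {
      for (a2 in seq_len(nrow(arcs))) {
        if (a1 == a2) next
        res <- add_reticulation(net, arcs[a1, ], arcs[a2, ])
        if (!is.null(res)) { net <- res; done <- TRUE; break }
      }
      if (done) break
    }
    if (!done) stop("could not add reticulation ", i)
  }
  net
}

caterpillar_tree <- function(labels) {
  n <- length(labels)
  if (n == 1) {
    return(rooted_network(rbind(c("r", "L1")),
                          stats::setNames(labels, "L1")))
  }
  arcs <- rbind(c("r", "i1"))
  for (j in seq_len(n - 1)) {
    arcs <- rbind(arcs, c(paste0("i", j), paste0("L", j)))
    if (j < n - 1) {
      arcs <- rbind(arcs, c(paste0("i", j), paste0("i", j + 1)))
    } else {
      arcs <- rbind(arcs, c(paste0("i", j), paste0("L", n)))
    }
  }
  rooted_network(arcs, stats::setNames(labels, paste0("L", seq_len(n))))
}

#' Seeded random network generator
#'
#' Builds a uniform-attachment random rooted binary tree on `n` leaves, then
#' adds `k` reticulations by subdividing a random ordered pair of distinct
#' edges and connecting the two subdivision nodes, rejecting and resampling
#' any addition that does not produce a valid network (bounded retries).
#' Deterministic per seed; the global RNG state is restored on exit.
#'
#' @param n number of leaves (>= 1; >= 2 recommended).
#' @param k reticulation number (>= 0).
#' @param seed integer seed.
#' @param labels optional taxon labels.
#' @return a valid `rooted_network` in tier (n, k).
#' @export
random_network <- function(n, k, seed, labels = NULL) {
  labels <- default_labels(n, labels)
  with_seed(seed, {
    net <- random_tree(labels)
    for (i in seq_len(k)) {
      for (try in 1:1000) {
        arcs <- net$arcs
        a1 <- sample.int(nrow(arcs), 1)
        a2 <- sample.int(nrow(arcs), 1)
        if (a1 == a2) next
        res <- add_reticulation(net, arcs[a1, ], arcs[a2, ])
        if (!is.null(res)) { net <- res; break }
        if (try == 1000) stop("could not add reticulation after 1000 tries")
      }
    }
    net
  })
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_tree <- function(labels) {
  n <- length(labels)
  if (n == 1) {
    return(rooted_network(rbind(c("r", "L1")), stats::setNames(labels, "L1")))
  }
  perm <- sample(labels)
  net <- rooted_network(rbind(c("r", "v1"), c("v1", "L1"), c("v1", "L2")),
                        stats::setNames(perm[1:2], c("L1", "L2")))
  for (i in seq_len(n - 2) + 2) {
    j <- sample.int(nrow(net$arcs), 1)
    e <- net$arcs[j, ]
    mid <- fresh_node_id(net)
    leaf_id <- paste0("L", i)
    arcs <- net$arcs[-j, , drop = FALSE]
    arcs <- rbind(arcs, c(e[1], mid), c(mid, e[2]), c(mid, leaf_id))
    net <- rooted_network(arcs, c(net$labels,
                                  stats::setNames(perm[i], leaf_id)))
  }
  net
}

#' Named fixture networks
#'
#' Small hand-constructed networks used throughout the theory:
#' `exceptional_two_leaf` -- the two-leaf tier-1 network (a triangle over a
#' cherry) admitting no nontrivial tail move, whose one nontrivial head move
#' cannot be simulated by tail moves; `exceptional_one_leaf` -- the one-leaf
#' tier-2 network all of whose valid head moves yield isomorphic networks;
#' `triangle_net` -- a three-leaf tier-1 network containing one triangle;
#' `stacked_triangles` -- a three-leaf tier-2 network with two triangles.
#' The unrootable five-node fixture lives in [unrootable_fixture()].
#'
#' @param name fixture name; omit for the full named list.
#' @return a `rooted_network`, or a named list of them.
#' @export
fixtures <- function(name = NULL) {
  all <- list(
    exceptional_two_leaf = rooted_network(
      rbind(c("r", "a"), c("a", "u"), c("a", "c"), c("u", "c"),
            c("u", "x"), c("c", "y")),
      c(x = "x", y = "y")),
    exceptional_one_leaf = rooted_network(
      rbind(c("r", "a"), c("a", "b"), c("a", "r2"), c("b", "r1"),
            c("b", "r2"), c("r2", "r1"), c("r1", "x")),
      c(x = "x")),
    triangle_net = rooted_network(
      rbind(c("r", "g"), c("g", "z"), c("g", "a"), c("a", "u"), c("a", "c"),
            c("u", "c"), c("u", "x"), c("c", "y")),
      c(x = "x", y = "y", z = "z")),
    stacked_triangles = rooted_network(
      rbind(c("r", "a"), c("a", "u1"), c("a", "c1"), c("u1", "c1"),
            c("u1", "x"), c("c1", "d"), c("d", "u2"), c("d", "c2"),
            c("u2", "c2"), c("u2", "y"), c("c2", "z")),
      c(x = "x", y = "y", z = "z"))
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all)) stop("unknown fixture: ", name)
  all[[name]]
}

# canonical forms of the two excluded networks, computed lazily
exceptional_canonicals <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixtures()
      cache <<- c(canonical_form(fx$exceptional_two_leaf),
                  canonical_form(fx$exceptional_one_leaf))
    }
    cache
  }
})

is_exceptional_network <- function(net) {
  ts <- tier_signature(net)
  if (!((ts$n_leaves == 2 && ts$k == 1) || (ts$n_leaves == 1 && ts$k == 2))) {
    return(FALSE)
  }
  # compare structurally, ignoring the taxon names
  anon <- rooted_network(net$arcs,
                         stats::setNames(paste0("t", seq_along(net$labels)),
                                         names(net$labels)[order(net$labels)]))
  fx <- if (ts$k == 1) fixtures("exceptional_two_leaf")
        else fixtures("exceptional_one_leaf")
  fx <- rooted_network(fx$arcs,
                       stats::setNames(paste0("t", seq_along(fx$labels)),
                                       names(fx$labels)[order(fx$labels)]))
  # structural comparison must ignore which taxon sits where: try all
  # assignments of the (at most 2) labels
  perms <- if (ts$n_leaves == 2) list(1:2, 2:1) else list(1L)
  for (p in perms) {
    relab <- fx
    relab$labels[] <- paste0("t", p)
    if (is_isomorphic(anon, relab)$isomorphic) return(TRUE)
  }
  FALSE
}
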