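test_that("movability follows the root/reticulation/triangle rules", {
  net <- fixtures("exceptional_two_leaf") # triangle a,u,c over leaves x,y
  expect_equal(is_movable(net, c("r", "a"))$reason, "root-tail")
  expect_equal(is_movable(net, c("c", "y"))$reason, "reticulation-tail")
  # (u, x): u sits in the triangle, head x outside it -> non-movable
  expect_equal(is_movable(net, c("u", "x"))$reason, "triangle-parallel")
  # bottom and long edge of the triangle are movable
  expect_true(is_movable(net, c("u", "c"))$movable)
  expect_true(is_movable(net, c("a", "c"))$movable)
})

test_that("find_triangles matches construction", {
  expect_length(find_triangles(three_leaf_tree()), 0)
  tr <- find_triangles(fixtures("triangle_net"))
  expect_length(tr, 1)
  expect_equal(tr[[1]], list(top = "a", side = "u", bottom_head = "c"))
  expect_length(find_triangles(fixtures("stacked_triangles")), 2)
})

test_that("tail move checks: root-edge target ok, cycle and parallel refused", {
  net <- fixtures("triangle_net")
  # a movable tail can always be moved to the root edge
  expect_true(check_tail_move(net, c("u", "c"), c("r", "g"))$ok)
  # target below the moving head -> cycle
  expect_equal(check_tail_move(net, c("g", "a"), c("u", "x"))$violation,
               "cycle")
  # target head equal to the moving head -> parallel
  expect_equal(check_tail_move(net, c("u", "c"), c("a", "c"))$violation,
               "parallel")
})

test_that("applying a tail move: cherry swap, conservation, reversibility", {
  t1 <- three_leaf_tree(c("x", "y"), "z") # ((x,y),z)
  # move the tail of (b, C1)=(b, x) to the arc above z
  res <- apply_tail_move(t1, net_move("tail", c("b", "C1"), c("a", "C3")))
  expect_iso(res, three_leaf_tree(c("x", "z"), "y"))

  for (s in 1:5) {
    net <- random_network(3, 1, 600 + s)
    mvs <- enumerate_moves(net, "tail", nontrivial = TRUE)
    for (m in mvs[seq_len(min(4, length(mvs)))]) {
      res <- apply_tail_move(net, m)
      expect_equal(unclass(tier_signature(res)), unclass(tier_signature(net)))
      back <- apply_tail_move(res, attr(res, "inverse"))
      expect_iso(net, back)
    }
  }
})

test_that("head moves require a reticulation head and refuse cycles", {
  t1 <- three_leaf_tree()
  expect_equal(check_head_move(t1, c("b", "C1"), c("a", "C3"))$violation,
               "not-reticulation-edge")
  net <- fixtures("triangle_net")
  # moving the head of (a, c) to an edge above its tail creates a cycle
  expect_equal(check_head_move(net, c("a", "c"), c("r", "g"))$violation,
               "cycle")
  # a valid head move applies, conserves the tier and reverses
  mvs <- enumerate_moves(net, "head", nontrivial = TRUE)
  expect_gt(length(mvs), 0)
  res <- apply_head_move(net, mvs[[1]])
  expect_equal(unclass(tier_signature(res)), unclass(tier_signature(net)))
  back <- apply_head_move(res, attr(res, "inverse"))
  expect_iso(net, back)
})

test_that("closed-form checks agree with the apply-then-validate oracle", {
  for (nk in list(c(2, 1), c(3, 1), c(2, 2))) {
    for (net in unname(tiers(nk[1], nk[2]))) {
      arcs <- net$arcs
      for (i in seq_len(nrow(arcs))) {
        for (j in seq_len(nrow(arcs))) {
          if (i == j) next
          e <- arcs[i, ]; f <- arcs[j, ]
          expect_equal(check_tail_move(net, e, f)$ok,
                       oracle_move_valid(net, e, f, "tail"),
                       info = paste("tail", paste(e, collapse = ">"),
                                    paste(f, collapse = ">")))
          expect_equal(check_head_move(net, e, f)$ok,
                       oracle_move_valid(net, e, f, "head"),
                       info = paste("head", paste(e, collapse = ">"),
                                    paste(f, collapse = ">")))
        }
      }
    }
  }
})

test_that("move distances: sibling edge is distance 1, deeper targets more", {
  t1 <- three_leaf_tree()
  # relocating a tail onto the other child edge of the same node is the
  # trivial distance-0 move; the sibling edge (parent to sibling) is the
  # distance-1 rNNI case
  expect_equal(move_distance(t1, net_move("tail", c("b", "C1"), c("b", "C2"))), 0L)
  expect_equal(move_distance(t1, net_move("tail", c("b", "C1"), c("a", "C3"))), 1L)
  expect_equal(move_distance(t1, net_move("tail", c("b", "C1"), c("r", "a"))), 1L)
  ct <- caterpillar_tree(c("a", "b", "c", "d"))
  expect_equal(move_distance(ct, net_move("tail", c("i3", "L3"), c("r", "i1"))), 2L)
  expect_equal(move_distance(ct, net_move("tail", c("i3", "L3"), c("i1", "L1"))), 2L)
})

test_that("move enumeration: class contents and the exceptional fixture", {
  expect_length(enumerate_moves(three_leaf_tree(), "head"), 0)
  exc <- fixtures("exceptional_two_leaf")
  expect_length(enumerate_moves(exc, "tail", nontrivial = TRUE), 0)
  h1 <- enumerate_moves(exc, "head1", nontrivial = TRUE)
  expect_length(h1, 1)
  expect_equal(classify_head1(exc, h1[[1]])$case, "a")
  # rspr = tail + head, rnni = distance-1 subset
  net <- fixtures("triangle_net")
  n_rspr <- length(enumerate_moves(net, "rspr"))
  expect_equal(n_rspr, length(enumerate_moves(net, "tail")) +
                 length(enumerate_moves(net, "head")))
  expect_lte(length(enumerate_moves(net, "rnni")), n_rspr)
})

test_that("every tree node has a movable child edge (Obs 2.10)", {
  for (nk in list(c(3, 1), c(2, 2))) {
    for (net in unname(tiers(nk[1], nk[2]))) {
      for (v in net_tree_nodes(net)) {
        kids <- net_children(net, v)
        expect_true(any(vapply(kids, function(c2)
          is_movable(net, c(v, c2))$movable, logical(1))))
      }
    }
  }
})

test_that("an LCA has a movable child edge not above both nodes (Lemma 2.12)", {
  for (net in unname(tiers(2, 2))) {
    leaves <- net_leaves(net)
    for (x in leaves) for (y in leaves) {
      if (x >= y) next
      ls <- lca_set(net, x, y)
      if (x %in% ls || y %in% ls) next
      for (l in ls) {
        kids <- net_children(net, l)
        good <- vapply(kids, function(c2) {
          is_movable(net, c(l, c2))$movable &&
            !(is_above(net, c2, x) && is_above(net, c2, y))
        }, logical(1))
        expect_true(any(good))
      }
    }
  }
})
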