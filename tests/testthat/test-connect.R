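test_that("frontier initialisation and its error conditions", {
  A <- random_network(3, 1, 11)
  B <- random_network(3, 1, 12)
  st <- init_frontier(A, B)
  expect_s3_class(st, "frontier_state")
  expect_length(st$YA, 3)
  expect_setequal(unname(A$labels[names(st$phi)]),
                  unname(B$labels[unname(st$phi)]))
  expect_error(init_frontier(A, random_network(3, 2, 13)), "tier mismatch")
  expect_error(init_frontier(A, random_network(3, 1, 13,
                                               labels = c("p", "q", "s"))),
               "tier mismatch")
  exc <- unname(tiers(2, 1))
  expect_error(init_frontier(exc[[1]], exc[[2]]), class = "excluded_instance")
})

test_that("extend_frontier strictly shrinks the complement in tail mode", {
  A <- random_network(4, 2, 21)
  B <- random_network(4, 2, 22)
  st <- init_frontier(A, B)
  while (length(st$A$nodes) - length(st$YA) >= 2) {
    before <- length(st$YA)
    st <- extend_frontier(st)
    expect_gt(length(st$YA), before)
    expect_lte(length(attr(st, "last_moves")), 3)
    # Y stays downward-closed on both sides
    for (v in st$YA) expect_true(all(net_children(st$A, v) %in% st$YA))
    for (v in st$YB) expect_true(all(net_children(st$B, v) %in% st$YB))
  }
})

test_that("tail_connect: trivial, exact-distance and random cases", {
  A <- random_network(3, 1, 31)
  expect_length(tail_connect(A, A), 0)

  t1 <- three_leaf_tree(c("x", "y"), "z")
  t2 <- three_leaf_tree(c("x", "z"), "y")
  seqm <- tail_connect(t1, t2)
  expect_lte(length(seqm), 9)
  expect_iso(replay_moves(t1, seqm), t2)
  expect_equal(exact_distance(t1, t2, "tail"), 1L)

  for (s in 1:8) {
    A <- random_network(4, 2, 4100 + s)
    B <- random_network(4, 2, 4200 + s)
    seqm <- tail_connect(A, B)
    expect_lte(length(seqm), 3 * (4 + 4))
    cur <- A
    for (m in seqm) {
      expect_equal(m$kind, "tail")
      cur <- apply_tail_move(cur, m) # every prefix valid by construction
    }
    expect_iso(cur, B)
  }
})

test_that("rspr_connect handles all tiers including the exceptional pair", {
  exc <- unname(tiers(2, 1))
  seqm <- rspr_connect(exc[[1]], exc[[2]])
  expect_length(seqm, 1)
  expect_equal(seqm[[1]]$kind, "head")
  expect_iso(replay_moves(exc[[1]], seqm), exc[[2]])

  for (s in 1:8) {
    A <- random_network(4, 2, 4300 + s)
    B <- random_network(4, 2, 4400 + s)
    seqm <- rspr_connect(A, B)
    expect_lte(length(seqm), 2 * 4 + 3 * 2 - 1)
    expect_iso(replay_moves(A, seqm), B)
  }
})

test_that("the root-triangle swap is equivalent to the long-edge head move", {
  N <- rooted_network(rbind(
    c("b", "c"), c("c", "z"), c("c", "d"), c("z", "d"), c("z", "x"),
    c("d", "e"), c("x", "s"), c("x", "t"), c("e", "s2"), c("e", "t2")),
    c(s = "s", t = "t", s2 = "s2", t2 = "t2"))
  target <- apply_head_move(N, net_move("head", c("c", "d"), c("z", "x")))
  moves <- list()
  push <- function(m, res) moves[[length(moves) + 1]] <<-
    list(move = m, inverse = attr(res, "inverse"))
  res <- case_b_swap(N, "c", "z", "d", "x",
                     c("x", "s", "t", "s2", "t2"), c(X = "x"), push)
  expect_length(moves, 3)
  expect_iso(res$A, target)
})

test_that("decompose_tail_move: distance-1 hops with the same composite", {
  t1 <- three_leaf_tree()
  m <- net_move("tail", c("b", "C1"), c("a", "C3")) # already distance 1
  expect_length(decompose_tail_move(t1, m), 1)

  ct <- caterpillar_tree(c("a", "b", "c", "d", "e"))
  m <- net_move("tail", c("i4", "L4"), c("r", "i1")) # depth-3 tail to root arc
  dec <- decompose_tail_move(ct, m)
  expect_length(dec, 3)
  cur <- ct
  for (d in dec) {
    expect_equal(move_distance(cur, d), 1L)
    cur <- apply_tail_move(cur, d)
  }
  expect_iso(cur, apply_tail_move(ct, m))

  for (s in 1:6) {
    net <- random_network(4, 2, 4500 + s)
    mvs <- enumerate_moves(net, "tail", nontrivial = TRUE)
    m <- mvs[[1 + (s * 7) %% length(mvs)]]
    dec <- decompose_tail_move(net, m)
    expect_lte(length(dec), 4 + 3 * 2 - 1)
    cur <- net
    for (d in dec) {
      expect_equal(move_distance(cur, d), 1L)
      cur <- apply_tail_move(cur, d)
    }
    expect_iso(cur, apply_tail_move(net, m))
  }
})
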