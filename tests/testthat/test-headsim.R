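test_that("distance-1 head moves classify into the six patterns", {
  seen <- character(0)
  for (nk in list(c(3, 1), c(2, 2))) {
    for (net in unname(tiers(nk[1], nk[2]))) {
      for (m in enumerate_moves(net, "head1")) {
        cl <- classify_head1(net, m)
        expect_true(cl$case %in% letters[1:6])
        seen <- union(seen, cl$case)
        # flagged degeneracies produce isomorphic results
        if ((cl$case %in% c("a", "b") && cl$x_eq_y) ||
            (cl$case %in% c("d", "f") && cl$u_eq_y)) {
          expect_iso(net, apply_head_move(net, m))
        }
      }
    }
  }
  # the tiny tiers exercise most patterns
  expect_gte(length(seen), 4)
})

test_that("case (c) uses the one-move constructive shortcut", {
  found <- 0
  for (net in unname(tiers(2, 2))) {
    for (m in enumerate_moves(net, "head1", nontrivial = TRUE)) {
      if (classify_head1(net, m)$case != "c") next
      found <- found + 1
      s <- simulate_head1(net, m)
      expect_length(s, 1)
      expect_iso(replay_moves(net, s), apply_head_move(net, m))
    }
  }
  expect_gt(found, 0)
})

test_that("degenerate isomorphic head moves simulate as the empty sequence", {
  exc1 <- fixtures("exceptional_one_leaf")
  mvs <- enumerate_moves(exc1, "head1")
  expect_gt(length(mvs), 0)
  for (m in mvs) expect_length(simulate_head1(exc1, m), 0)
})

test_that("the exceptional two-leaf network refuses simulation", {
  exc <- fixtures("exceptional_two_leaf")
  m <- enumerate_moves(exc, "head1", nontrivial = TRUE)[[1]]
  expect_error(simulate_head1(exc, m), class = "exceptional_network")
})

test_that("simulations on sampled tier-(3,1) moves are short and faithful", {
  nets <- unname(tiers(3, 1))[c(2, 7, 13)]
  for (net in nets) {
    for (m in enumerate_moves(net, "head1", nontrivial = TRUE)) {
      s <- simulate_head1(net, m)
      expect_lte(length(s), 4)
      expect_iso(replay_moves(net, s), apply_head_move(net, m))
    }
  }
})

test_that("tail_reachable: identity, neighbours, and the exceptional pair", {
  net <- fixtures("triangle_net")
  expect_length(tail_reachable(net, net, cap = 2), 0)
  m <- enumerate_moves(net, "tail", nontrivial = TRUE)[[1]]
  nb <- apply_tail_move(net, m)
  p <- tail_reachable(net, nb, cap = 2)
  expect_length(p, 1)
  expect_iso(replay_moves(net, p), nb)
  exc <- unname(tiers(2, 1))
  expect_null(tail_reachable(exc[[1]], exc[[2]], cap = 8))
  expect_error(tail_reachable(exc[[1]], fixtures("triangle_net")),
               "tier mismatch")
})
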