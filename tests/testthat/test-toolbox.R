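test_that("tier enumeration counts and guards", {
  expect_length(tiers(2, 0), 1)
  expect_length(tiers(3, 0), 3)
  expect_length(tiers(1, 1), 0) # the one-leaf one-reticulation tier is empty
  expect_length(tiers(1, 2), 1) # exactly the one-leaf fixture
  expect_length(tiers(2, 1), 2)
  expect_error(enumerate_tier(6, 3), "size guard")
})

test_that("the constructive enumerator cross-checks the closure enumerator", {
  for (nk in list(c(2, 1), c(3, 1))) {
    a <- tiers(nk[1], nk[2])
    b <- enumerate_tier_constructive(nk[1], nk[2])
    expect_setequal(names(b), names(a)) # equality holds for k <= 1
  }
  # at k = 2 the constructive enumerator is provably incomplete (some
  # networks admit no reticulation-edge deletion), but never over-generates
  a <- tiers(2, 2)
  b <- enumerate_tier_constructive(2, 2)
  expect_true(all(names(b) %in% names(a)))
  expect_lt(length(b), length(a))
  one_leaf <- enumerate_tier_constructive(1, 2)
  expect_false(canonical_form(fixtures("exceptional_one_leaf")) %in%
                 names(one_leaf))
})

test_that("random networks are valid, in-tier, and seed-stable", {
  for (s in 1:10) {
    net <- random_network(4, 2, s)
    expect_length(validate_rooted(net), 0)
    ts <- tier_signature(net)
    expect_equal(c(ts$n_leaves, ts$k, ts$n_nodes, ts$n_edges),
                 c(4L, 2L, 12L, 13L))
  }
  expect_identical(canonical_form(random_network(4, 2, 77)),
                   canonical_form(random_network(4, 2, 77)))
  # the generator must not disturb the caller's RNG stream
  set.seed(5); a <- runif(1)
  set.seed(5); invisible(random_network(3, 1, 9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("exact distances: identity, neighbours, unreachable component", {
  net <- fixtures("triangle_net")
  expect_equal(exact_distance(net, net, "tail"), 0L)
  m <- enumerate_moves(net, "tail", nontrivial = TRUE)[[1]]
  expect_equal(exact_distance(net, apply_tail_move(net, m), "tail"), 1L)
  exc <- unname(tiers(2, 1))
  expect_identical(exact_distance(exc[[1]], exc[[2]], "tail", cap = 50), Inf)
  expect_equal(exact_distance(exc[[1]], exc[[2]], "rspr"), 1L)
})

test_that("fixture networks have their defining properties", {
  fx <- fixtures()
  for (net in fx) expect_length(validate_rooted(net), 0)
  expect_length(enumerate_moves(fx$exceptional_two_leaf, "tail",
                                nontrivial = TRUE), 0)
  expect_length(enumerate_moves(fx$exceptional_two_leaf, "head1",
                                nontrivial = TRUE), 1)
  expect_length(enumerate_moves(fx$exceptional_one_leaf, "head",
                                nontrivial = TRUE), 0)
  expect_error(fixtures("nope"), "unknown fixture")
})

test_that("tree restriction and agreement forests", {
  t1 <- three_leaf_tree(c("x", "y"), "z")
  r <- restrict_tree(t1, c("x", "z"))
  expect_equal(nrow(r$arcs), 2) # a cherry on x, z after suppression
  rr <- restrict_tree(t1, c("x", "rho"))
  expect_equal(nrow(rr$arcs), 1) # the root edge down to x

  # singletons always form an agreement forest
  expect_true(is_agreement_forest(
    list(t1, three_leaf_tree(c("x", "z"), "y")),
    list("x", "y", "z", "rho")))
  # the whole set agrees only for identical trees
  expect_true(is_agreement_forest(list(t1, t1), list(c("x", "y", "z", "rho"))))
  expect_false(is_agreement_forest(
    list(t1, three_leaf_tree(c("x", "z"), "y")),
    list(c("x", "y", "z", "rho"))))
})

test_that("MAF size: identity, different cherries, BFS cross-oracle", {
  t1 <- three_leaf_tree(c("x", "y"), "z")
  t2 <- three_leaf_tree(c("x", "z"), "y")
  expect_equal(maf_size_exhaustive(t1, t1), 1L)
  expect_equal(maf_size_exhaustive(t1, t2), 2L)
  t4 <- unname(tiers(4, 0))
  set.seed(42)
  idx <- cbind(sample(length(t4), 12, replace = TRUE),
               sample(length(t4), 12, replace = TRUE))
  for (r in seq_len(nrow(idx))) {
    a <- t4[[idx[r, 1]]]; b <- t4[[idx[r, 2]]]
    expect_equal(maf_size_exhaustive(a, b) - 1L,
                 exact_distance(a, b, "tail", cap = 6))
  }
})

test_that("mycorrhizal gluing produces valid networks", {
  R <- rooted_network(rbind(c("r", "a"), c("a", "b"), c("a", "c"),
                            c("b", "c"), c("b", "p1"), c("c", "p2")),
                      c(p1 = "s1", p2 = "s2"))
  T1 <- unname(tiers(3, 0))
  Ta <- enumerate_tier(3, 0, labels = c("a1", "a2", "a3"))
  Tb <- enumerate_tier(3, 0, labels = c("b1", "b2", "b3"))
  M <- build_mycorrhizal(list(Ta[[1]], Tb[[1]]), R)
  ts <- tier_signature(M)
  expect_equal(c(ts$n_leaves, ts$k), c(6L, 1L))
  # mycorrhizal tree: one component on a trivial root component
  Rt <- rooted_network(rbind(c("r", "p1")), c(p1 = "s1"))
  Mt <- build_mycorrhizal(list(Ta[[2]]), Rt)
  expect_length(validate_rooted(Mt), 0)
  expect_iso(Mt, rooted_network(Ta[[2]]$arcs, Ta[[2]]$labels))
})
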