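test_that("validation flags the defining violations", {
  expect_length(validate_rooted(cherry_net()), 0)

  dup <- cherry_net()
  dup$arcs <- rbind(dup$arcs, c("a", "x"))
  expect_match(paste(validate_rooted(dup), collapse = " "), "parallel")

  cyc <- structure(list(
    nodes = c("r", "a", "b", "c", "x"),
    arcs = rbind(c("r", "a"), c("a", "b"), c("b", "c"), c("c", "b"),
                 c("a", "x")),
    labels = c(x = "x")), class = "rooted_network")
  expect_match(paste(validate_rooted(cyc), collapse = " "), "cycle|degree")
})

test_that("tier signatures satisfy the counting identities", {
  ts <- tier_signature(fixtures("exceptional_two_leaf"))
  expect_equal(unclass(ts)[c("n_leaves", "k", "n_nodes", "n_edges")],
               list(n_leaves = 2L, k = 1L, n_nodes = 6L, n_edges = 6L))
  ts3 <- tier_signature(three_leaf_tree())
  expect_equal(unclass(ts3)[c("n_leaves", "k", "n_nodes", "n_edges")],
               list(n_leaves = 3L, k = 0L, n_nodes = 6L, n_edges = 5L))
  ts12 <- tier_signature(fixtures("exceptional_one_leaf"))
  expect_equal(unclass(ts12)[c("n_leaves", "k", "n_nodes", "n_edges")],
               list(n_leaves = 1L, k = 2L, n_nodes = 6L, n_edges = 7L))
  # both identities on random networks of several tiers
  for (s in 1:5) {
    net <- random_network(4, 2, 100 + s)
    ts <- tier_signature(net)
    expect_equal(ts$n_nodes, 2 * ts$n_leaves + 2 * ts$k)
    expect_equal(ts$n_edges, 2 * ts$n_leaves + 3 * ts$k - 1)
  }
})

test_that("isomorphism respects arcs and labels, mapping returned", {
  net <- fixtures("triangle_net")
  self <- is_isomorphic(net, net)
  expect_true(self$isomorphic)
  expect_equal(unname(self$mapping[net$nodes]), net$nodes)

  ren <- rooted_network(matrix(paste0("N", net$arcs), ncol = 2),
                        stats::setNames(unname(net$labels),
                                        paste0("N", names(net$labels))))
  r <- is_isomorphic(net, ren)
  expect_true(r$isomorphic)
  moved <- paste(r$mapping[net$arcs[, 1]], r$mapping[net$arcs[, 2]])
  expect_setequal(moved, paste(ren$arcs[, 1], ren$arcs[, 2]))

  expect_false(is_isomorphic(three_leaf_tree(c("x", "y"), "z"),
                             three_leaf_tree(c("x", "z"), "y"))$isomorphic)
})

test_that("canonical_form equality coincides with isomorphism on small tiers", {
  for (nk in list(c(2, 1), c(1, 2), c(3, 1))) {
    nets <- unname(tiers(nk[1], nk[2]))
    toks <- vapply(nets, canonical_form, character(1))
    expect_false(anyDuplicated(toks) > 0) # enumeration is duplicate-free
    for (i in seq_along(nets)) {
      for (j in seq_along(nets)) {
        expect_equal(identical(toks[i], toks[j]),
                     is_isomorphic(nets[[i]], nets[[j]])$isomorphic)
      }
    }
  }
  # relabellings collide, distinct cherries do not
  t1 <- three_leaf_tree()
  t1b <- rooted_network(matrix(paste0("Q", t1$arcs), ncol = 2),
                        stats::setNames(unname(t1$labels),
                                        paste0("Q", names(t1$labels))))
  expect_identical(canonical_form(t1), canonical_form(t1b))
  expect_false(identical(canonical_form(three_leaf_tree(c("x", "y"), "z")),
                         canonical_form(three_leaf_tree(c("x", "z"), "y"))))
})

test_that("ancestry and LCA sets behave as specified", {
  ch <- cherry_net()
  expect_true(is_above(ch, "a", "x"))
  expect_true(is_above(ch, "x", "x")) # reflexive
  expect_false(is_above(ch, "x", "y"))
  expect_equal(lca_set(ch, "x", "y"), "a")
  expect_equal(lca_set(ch, "a", "x"), "a") # u above v -> {u}
  expect_error(is_above(ch, "nope", "x"), "unknown node")

  dd <- diamond_net()
  expect_setequal(lca_set(dd, "r1", "r2"), c("p1", "p2"))
  # members pairwise incomparable; every common ancestor above some member
  ls <- lca_set(dd, "r1", "r2")
  for (u in ls) for (v in ls) if (u != v) expect_false(is_above(dd, u, v))
  common <- Filter(function(a) is_above(dd, a, "r1") && is_above(dd, a, "r2"),
                   dd$nodes)
  for (a in common) {
    expect_true(any(vapply(ls, function(m) is_above(dd, a, m), logical(1))))
  }
})

test_that("eNewick round trips, plain Newick, and parse errors", {
  ch <- read_enewick("((x,y));")
  expect_length(validate_rooted(ch), 0)
  expect_equal(length(net_children(ch, net_root(ch))), 1)

  # plain Newick gets a root edge added
  pl <- read_enewick("(x,(y,z));")
  expect_iso(pl, three_leaf_tree(c("y", "z"), "x"))

  for (s in 1:5) {
    net <- random_network(4, 2, 500 + s)
    expect_iso(net, read_enewick(write_enewick(net)))
  }
  expect_error(read_enewick("((x,y"), "';'")
  expect_error(read_enewick("((x,y,z));"), "non-binary")
  expect_silent(read_enewick("((x,y,z));", resolve = TRUE))
  expect_warning(read_enewick("((x:1.1,y:2));"), "discarded")
})

test_that("JSON dump round trips bit-exactly", {
  net <- fixtures("stacked_triangles")
  back <- read_net_json(write_net_json(net))
  expect_identical(back$labels[order(names(back$labels))],
                   net$labels[order(names(net$labels))])
  expect_setequal(paste(back$arcs[, 1], back$arcs[, 2]),
                  paste(net$arcs[, 1], net$arcs[, 2]))
  expect_identical(back$nodes, net$nodes)
})
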