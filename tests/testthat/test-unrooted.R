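test_that("unrooted validation accepts the single edge and flags violations", {
  single <- unrooted_network(rbind(c("x", "y")), c(x = "x", y = "y"))
  expect_length(validate_unrooted(single), 0)

  path3 <- structure(list(nodes = c("m", "x", "y"),
                          edges = rbind(c("m", "x"), c("m", "y")),
                          labels = c(x = "x", y = "y")),
                     class = "unrooted_network")
  expect_match(paste(validate_unrooted(path3), collapse = " "), "degree")

  disc <- structure(list(nodes = c("a", "b", "c", "d"),
                         edges = rbind(c("a", "b"), c("c", "d")),
                         labels = c(a = "a", b = "b", c = "c", d = "d")),
                    class = "unrooted_network")
  expect_match(paste(validate_unrooted(disc), collapse = " "), "connected")
})

test_that("bridge decomposition: trees, fixtures, underlying graphs", {
  utree <- underlying(three_leaf_tree())
  expect_equal(nrow(cut_edges(utree)), nrow(utree$edges))
  expect_equal(nrow(redundant_cut_edges(utree)), 0)
  expect_length(blobs(utree), 0)

  U <- unrootable_fixture()
  expect_equal(nrow(redundant_cut_edges(U)), 1)
  tcs <- terminal_components(U)
  expect_length(tcs, 1)
  expect_length(tcs[[1]]$nodes, 5)
  expect_equal(nrow(tcs[[1]]$incident_edges) - length(tcs[[1]]$nodes), 3)

  # underlying graphs of rooted networks never have redundant cut-edges
  for (s in 1:5) {
    UU <- underlying(random_network(4, 2, 800 + s))
    expect_equal(nrow(redundant_cut_edges(UU)), 0)
    expect_true(is_rootable(UU))
  }
})

test_that("terminal component count respects the k/3 bound", {
  for (s in 1:10) {
    UU <- underlying(random_network(3, 3, 900 + s))
    k <- nrow(UU$edges) - length(UU$nodes) + 1
    expect_lte(3 * length(terminal_components(UU)), k)
  }
  U <- unrootable_fixture()
  k <- nrow(U$edges) - length(U$nodes) + 1
  expect_lte(3 * length(terminal_components(U)), k)
})

test_that("rootability and orientation round trips", {
  utree <- underlying(three_leaf_tree())
  for (lf in unname(utree$labels)) {
    N <- orient(utree, lf)
    expect_length(validate_rooted(N), 0)
  }
  expect_false(is_rootable(unrootable_fixture()))
  expect_error(orient(unrootable_fixture(), "l1"), class = "not_rootable")
  expect_error(orient(utree, "nope"), "unknown leaf")

  for (s in 1:10) {
    UU <- underlying(random_network(4, 2, 850 + s))
    lf <- sort(unname(UU$labels))[1 + s %% 3]
    N <- orient(UU, lf)
    expect_length(validate_rooted(N), 0)
    expect_identical(canonical_form(underlying(N)), canonical_form(UU))
  }
})

test_that("rSPR moves project to SPR moves and the square commutes", {
  for (s in 1:8) {
    N <- random_network(4, 2, 750 + s)
    mvs <- enumerate_moves(N, "rspr", nontrivial = TRUE)
    m <- mvs[[1 + (3 * s) %% length(mvs)]]
    lhs <- underlying(apply_move(N, m))
    rhs <- apply_spr_move(underlying(N), project_move(m))
    expect_iso(lhs, rhs)
  }
})

test_that("SPR application: conservation, reversibility, rejection", {
  U <- underlying(random_network(3, 1, 41))
  nb <- enumerate_spr_moves(U)
  expect_gt(length(nb), 0)
  for (x in nb[seq_len(min(6, length(nb)))]) {
    expect_identical(u_tier(x$net), u_tier(U))
    back <- apply_spr_move(x$net, attr(x$net, "inverse"))
    expect_iso(back, U)
  }
  # a move that would disconnect the graph is rejected: detaching the
  # bridge side of a cut edge onto an edge of its own component
  expect_error(apply_spr(U, U$edges[1, 1], U$edges[1, ], U$edges[1, ]),
               "coincide")
})

test_that("stripping a terminal component works and is SPR distance 1", {
  U <- unrootable_fixture()
  st <- strip_terminal_component(U)
  expect_length(terminal_components(st$net), 0)
  expect_true(is_rootable(st$net))
  expect_identical(u_tier(st$net), u_tier(U))
  expect_equal(exact_spr_distance(U, st$net, cap = 3), 1L)
  expect_error(strip_terminal_component(st$net),
               class = "no_terminal_component")
  mr <- make_rootable(U)
  expect_length(mr$moves, 1)
  k <- nrow(U$edges) - length(U$nodes) + 1
  expect_lte(length(mr$moves), floor(k / 3))
})

test_that("spr_connect: soundness and the n + 8k/3 bound", {
  mkU <- function(n, k, s) {
    N <- random_network(n, k, s)
    attr(N, "root_label") <- "rt"
    underlying(N)
  }
  for (s in 1:6) {
    A <- mkU(4, 2, 5100 + s)
    B <- mkU(4, 2, 5200 + s)
    seqm <- spr_connect(A, B)
    expect_lte(length(seqm), 5 + (8 / 3) * 2)
    cur <- A
    for (m in seqm) cur <- apply_spr_move(cur, m)
    expect_iso(cur, B)
  }
  expect_length(spr_connect(A <- mkU(3, 1, 61), A), 0)
  # with an unrootable side: strips included, bound n + 8k/3
  U <- unrootable_fixture()
  N <- random_network(2, 3, 77, labels = c("l2", "l3"))
  attr(N, "root_label") <- "l1"
  B <- underlying(N)
  seqm <- spr_connect(U, B)
  expect_lte(length(seqm), 3 + (8 / 3) * 3)
  cur <- U
  for (m in seqm) cur <- apply_spr_move(cur, m)
  expect_iso(cur, B)
})

test_that("edge-list text format round trips", {
  U <- unrootable_fixture()
  back <- read_edgelist(write_edgelist(U))
  expect_identical(canonical_form(back), canonical_form(U))
  expect_identical(sort(unname(back$labels)), sort(unname(U$labels)))
})
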