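# Shared builders and a per-run cache for enumerated tiers.

cherry_net <- function() {
  rooted_network(rbind(c("rho", "a"), c("a", "x"), c("a", "y")),
                 c(x = "x", y = "y"))
}

three_leaf_tree <- function(cherry = c("x", "y"), third = "z") {
  rooted_network(rbind(c("r", "a"), c("a", "b"), c("a", "C3"),
                       c("b", "C1"), c("b", "C2")),
                 stats::setNames(c(cherry, third), c("C1", "C2", "C3")))
}

# two reticulations sharing both parents: lca_set(r1, r2) = {p1, p2}
diamond_net <- function() {
  rooted_network(rbind(c("r", "s"), c("s", "p1"), c("s", "p2"),
                       c("p1", "r1"), c("p1", "r2"), c("p2", "r1"),
                       c("p2", "r2"), c("r1", "x"), c("r2", "y")),
                 c(x = "x", y = "y"))
}

.tier_cache <- new.env(parent = emptyenv())
tiers <- function(n, k) {
  key <- paste0(n, "_", k)
  if (is.null(.tier_cache[[key]])) {
    .tier_cache[[key]] <- enumerate_tier(n, k)
  }
  .tier_cache[[key]]
}

expect_iso <- function(a, b) {
  expect_true(is_isomorphic(a, b)$isomorphic)
}
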