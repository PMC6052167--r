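test_that("grow_supernodes claims nodes round by round", {
  tt <- g_two_triangles()
  s <- grow_supernodes(tt, c(3, 4), o_max = 6)
  expect_equal(s$assignment, c(1, 1, 1, 2, 2, 2))
  # equal-weight tie between two seeds goes to the lower selection rank
  s <- grow_supernodes(g_path(3), c(1, 3), o_max = 6)
  expect_equal(s$assignment, c(1, 1, 2))
  # nodes beyond o_max rounds become periphery
  s <- grow_supernodes(g_path(5), 3, o_max = 1)
  expect_equal(s$assignment, c(NA, 1, 1, 1, NA))
  expect_error(grow_supernodes(tt, integer(0)), "non-empty")
  expect_error(grow_supernodes(tt, c(2, 2)), "distinct")
})

test_that("growth prefers the heavier super node and warns on unseeded components", {
  # node 3 touches seed-1 side with weight 3 and seed-2 side with weight 1
  g <- mk_graph(c(1, 2, 3, 3), c(3, 3, 4, 5), n = 5,
                w = c(2, 1, 1, 5))
  s <- grow_supernodes(g, c(1, 5), o_max = 1, refine = FALSE)
  expect_equal(s$assignment[3], 2L)  # weight 5 to SN2 beats 2 to SN1
  two_comp <- mk_graph(c(1, 3), c(2, 4))
  expect_warning(s <- grow_supernodes(two_comp, 1, o_max = 6),
                 "without a seed")
  expect_equal(s$assignment, c(1, 1, NA, NA))
})

test_that("the refinement sweep fixes single-edge misclaims but keeps examples", {
  # all hand examples above are invariant under refinement
  tt <- g_two_triangles()
  expect_equal(grow_supernodes(tt, c(3, 4))$assignment,
               grow_supernodes(tt, c(3, 4), refine = FALSE)$assignment)
  # a node grabbed by a lone cross-community edge is pulled back once its
  # real neighborhood is assigned
  g <- mk_graph(c(1, 1, 2, 2, 3, 4, 4, 4, 5), c(2, 3, 3, 7, 7, 7, 5, 6, 6),
                n = 7)
  s0 <- grow_supernodes(g, c(4, 1), o_max = 6, refine = FALSE)
  s1 <- grow_supernodes(g, c(4, 1), o_max = 6)
  expect_equal(s0$assignment[7], 1L)  # round 1: only seed 4 adjacent
  expect_equal(s1$assignment[7], 2L)  # sweep: 2 edges into the triangle win
})

test_that("build_supernode_network aggregates crossing weights, no self loops", {
  tt <- g_two_triangles()
  s <- grow_supernodes(tt, c(3, 4))
  snw <- build_supernode_network(tt, s)
  expect_equal(igraph::vcount(snw$graph), 2)
  expect_equal(igraph::ecount(snw$graph), 1)
  expect_equal(igraph::E(snw$graph)$weight, 1)
  # all nodes in one super node -> a single isolated node
  s1 <- grow_supernodes(tt, 3)
  snw1 <- build_supernode_network(tt, s1)
  expect_equal(igraph::vcount(snw1$graph), 1)
  expect_equal(igraph::ecount(snw1$graph), 0)
  # path split in half crosses once
  p4 <- g_path(4)
  sp <- grow_supernodes(p4, c(1, 4), o_max = 6)
  snwp <- build_supernode_network(p4, sp)
  expect_equal(igraph::E(snwp$graph)$weight, 1)
})

test_that("edge weight is conserved across compression", {
  for (seed in 1:8) {
    g <- random_gnp(40, 0.1, seed)
    S <- 2 + seed %% 5
    suppressWarnings(s <- grow_supernodes(g, corehd_seeds(g, S),
                                          o_max = 1 + seed %% 3))
    snw <- build_supernode_network(g, s)
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- igraph::E(g)$weight
    a <- s$assignment[el[, 1]]; b <- s$assignment[el[, 2]]
    periph <- is.na(a) | is.na(b)
    within <- !periph & a == b
    expect_equal(sum(igraph::E(snw$graph)$weight) + sum(w[within]) +
                   sum(w[periph]),
                 sum(w))
    # membership sets plus periphery partition the nodes
    all_nodes <- sort(c(unlist(snw$membership, use.names = FALSE),
                        snw$periphery))
    expect_equal(all_nodes, seq_len(igraph::vcount(g)))
  }
})

test_that("assigned set grows with o_max and covers seeded components", {
  g <- random_gnp(60, 0.05, seed = 4)
  seeds <- corehd_seeds(g, 3)
  prev <- 0
  for (o in 1:6) {
    suppressWarnings(s <- grow_supernodes(g, seeds, o_max = o))
    cur <- sum(!is.na(s$assignment))
    expect_gte(cur, prev)
    prev <- cur
  }
  comp <- igraph::components(g)$membership
  suppressWarnings(s <- grow_supernodes(g, seeds, o_max = 60))
  seeded <- comp %in% comp[seeds]
  expect_true(all(!is.na(s$assignment[seeded])))
  expect_true(all(is.na(s$assignment[!seeded])))
})

test_that("S = N compression is the identity", {
  g <- random_gnp(25, 0.15, seed = 6)
  s <- grow_supernodes(g, seq_len(25))
  snw <- build_supernode_network(g, s)
  expect_equal(igraph::ecount(snw$graph), igraph::ecount(g))
  key <- function(gr) {
    el <- igraph::as_edgelist(gr, names = FALSE)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  expect_setequal(key(snw$graph), key(g))
  z <- c(rep(1L, 10), rep(2L, 15))
  expect_equal(lift_partition(s, z), z)
})

test_that("lift_partition relabels members and pools the periphery", {
  tt <- g_two_triangles()
  s <- grow_supernodes(tt, c(3, 4))
  expect_equal(lift_partition(s, c(1, 2)), c(1, 1, 1, 2, 2, 2))
  expect_equal(lift_partition(s, c(1, 1)), rep(1L, 6))
  sp <- grow_supernodes(g_path(5), 3, o_max = 1)
  z <- lift_partition(sp, 1L)
  expect_equal(z[2:4], rep(z[3], 3))
  expect_equal(z[1], z[5])
  expect_false(z[1] == z[3])  # periphery label is fresh
  expect_error(lift_partition(s, 1L), "one label per super node")
})
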