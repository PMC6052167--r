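triangle <- function() mk_graph(c(1, 1, 2), c(2, 3, 3))
two_triangles_disjoint <- function() {
  mk_graph(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))
}

test_that("modularity_score reproduces closed-form fixtures", {
  expect_equal(modularity_score(triangle(), rep(1, 3)), 0)
  expect_equal(modularity_score(triangle(), 1:3), -1 / 3)
  expect_equal(modularity_score(two_triangles_disjoint(),
                                c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_error(modularity_score(mk_graph(integer(0), integer(0), n = 3),
                                rep(1, 3)), "no edges")
  expect_error(modularity_score(triangle(), rep(1, 3), gamma = 0), "positive")
})

test_that("modularity_score matches igraph across graphs, partitions, gammas", {
  for (seed in 1:10) {
    g <- random_gnp(30, 0.15, seed)
    z <- withr::with_seed(seed, sample(1:4, 30, replace = TRUE))
    for (gamma in c(0.3, 1, 2.2)) {
      expect_equal(modularity_score(g, z, gamma),
                   igraph::modularity(g, z, resolution = gamma,
                                      weights = igraph::E(g)$weight),
                   tolerance = 1e-12)
    }
  }
  # weighted graph: M' is total weight, not edge count
  gw <- mk_graph(c(1, 1, 2, 4, 4, 5, 3), c(2, 3, 3, 5, 6, 6, 4),
                 w = c(3, 3, 3, 3, 3, 3, 1))
  z <- c(1, 1, 1, 2, 2, 2)
  expect_equal(modularity_score(gw, z, 1),
               igraph::modularity(gw, z, weights = igraph::E(gw)$weight))
  # invariance under relabeling and node reordering of the partition labels
  g <- random_gnp(25, 0.2, seed = 3)
  z <- withr::with_seed(1, sample(1:3, 25, replace = TRUE))
  expect_equal(modularity_score(g, z), modularity_score(g, 4 - z))
})

test_that("all-in-one modularity is exactly zero at gamma 1", {
  for (seed in 1:10) {
    g <- random_gnp(20 + seed, 0.2, seed)
    expect_equal(modularity_score(g, rep(1, igraph::vcount(g))), 0,
                 tolerance = 1e-14)
  }
})

test_that("detect_modularity finds exhaustively verified optima", {
  # brute-force search over all 203 partitions of 6 nodes
  g <- two_triangles_disjoint()
  qs <- vapply(all_partitions(6), function(z) modularity_score(g, z),
               numeric(1))
  expect_equal(max(qs), 0.5)
  best <- all_partitions(6)[[which.max(qs)]]
  expect_equal(best, c(1, 1, 1, 2, 2, 2))
  expect_equal(sum(abs(qs - 0.5) < 1e-12), 1)  # unique maximum
  z <- detect_modularity(g, 1, rng_seed = 7)
  expect_equal(z, c(1, 1, 1, 2, 2, 2))
  # complete graph: any split is worse than one community
  k4 <- mk_graph(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))
  qs4 <- vapply(all_partitions(4), function(z) modularity_score(k4, z),
                numeric(1))
  expect_true(all(qs4[-1] < 0))
  expect_equal(max(detect_modularity(k4, 1, rng_seed = 3)), 1)
})

test_that("detect_modularity is seed-deterministic and beats trivial partitions", {
  g <- random_gnp(80, 0.08, seed = 11)
  expect_identical(detect_modularity(g, 1, 5), detect_modularity(g, 1, 5))
  for (gamma in c(0.5, 1, 2)) {
    z <- detect_modularity(g, gamma, 9)
    q <- modularity_score(g, z, gamma)
    expect_gte(q, modularity_score(g, rep(1, 80), gamma))
    expect_gte(q, modularity_score(g, 1:80, gamma))
  }
})

test_that("estimate_block_matrix is the Bernoulli MLE", {
  g <- two_triangles_disjoint()
  expect_equal(estimate_block_matrix(g, c(1, 1, 1, 2, 2, 2)),
               diag(2))
  expect_equal(estimate_block_matrix(triangle(), rep(1, 3)),
               matrix(1, 1, 1))
  one <- mk_graph(integer(0), integer(0), n = 1)
  expect_equal(estimate_block_matrix(one, 1L), matrix(0, 1, 1))
  gw <- mk_graph(1, 2, w = 2)
  expect_error(estimate_block_matrix(gw, c(1, 1)), "unweighted")
})

test_that("sbm_log_likelihood matches the brute-force pair product", {
  g <- two_triangles_disjoint()
  z <- c(1, 1, 1, 2, 2, 2)
  expect_equal(sbm_log_likelihood(g, z, estimate_block_matrix(g, z)), 0)
  expect_equal(sbm_log_likelihood(mk_graph(1, 2), c(1, 1),
                                  matrix(0.5, 1, 1)),
               log(0.5))
  empty3 <- mk_graph(integer(0), integer(0), n = 3)
  expect_equal(sbm_log_likelihood(empty3, rep(1, 3), matrix(0, 1, 1)), 0)
  # contradiction sentinel
  expect_equal(sbm_log_likelihood(mk_graph(1, 2), c(1, 1),
                                  matrix(0, 1, 1)), -Inf)
  for (seed in 1:12) {
    n <- 4 + seed %% 4  # up to 7 nodes
    g <- random_gnp(n, 0.4, seed)
    z <- withr::with_seed(seed, sample(1:2, n, replace = TRUE))
    pi_r <- withr::with_seed(seed + 100, {
      m <- matrix(runif(4, 0.05, 0.95), 2, 2); (m + t(m)) / 2
    })
    expect_equal(sbm_log_likelihood(g, z, pi_r), oracle_sbm_ll(g, z, pi_r),
                 tolerance = 1e-10)
  }
})

test_that("the MLE block matrix maximizes the likelihood", {
  g <- random_gnp(12, 0.3, seed = 8)
  z <- withr::with_seed(2, sample(1:2, 12, replace = TRUE))
  pi_hat <- estimate_block_matrix(g, z)
  ll_hat <- sbm_log_likelihood(g, z, pi_hat)
  for (d in c(-0.1, -0.02, 0.02, 0.1)) {
    pi_p <- pmin(pmax(pi_hat + d, 0.001), 0.999)
    expect_gte(ll_hat, sbm_log_likelihood(g, z, pi_p))
  }
})

test_that("matched_block_count counts distinct labels", {
  expect_equal(matched_block_count(c(1, 1, 2, 2)), 2)
  expect_equal(matched_block_count(rep(7, 5)), 1)
  expect_equal(matched_block_count(c(1, 2, 3, 2)), 3)
  expect_error(matched_block_count(integer(0)), "non-empty")
})

test_that("matched_resolution picks the gamma agreeing with the reference", {
  # unequal block sizes so the community-size ranking carries information
  g <- withr::with_seed(21, {
    igraph::sample_sbm(210, matrix(c(0.3, 0.01, 0.01,
                                     0.01, 0.3, 0.01,
                                     0.01, 0.01, 0.3), 3),
                       block.sizes = c(30, 60, 120))
  })
  g <- igraph::set_edge_attr(g, "weight", value = rep(1, igraph::ecount(g)))
  truth <- rep(1:3, c(30, 60, 120))
  mr <- matched_resolution(g, truth, gammas = c(0.1, 0.5, 1, 2),
                           runs_per_gamma = 2, rng_seed = 5)
  z_star <- detect_modularity(g, mr$gamma_star, 77)
  expect_gte(nmi(z_star, truth), 0.9)
  expect_equal(nrow(mr$tau_curve), 4)
  # perfect agreement at some gamma implies tau 1 there
  expect_gte(max(mr$tau_curve$mean_tau), 0.99)
  expect_error(matched_resolution(g, truth, gammas = numeric(0)),
               "non-empty")
})

test_that("fully tied rankings give tau 0 with a warning", {
  g <- mk_graph(c(1, 1, 2, 3), c(2, 3, 3, 4))
  expect_warning(
    mr <- matched_resolution(g, rep(1L, 4), gammas = 0.05,
                             runs_per_gamma = 1, rng_seed = 1),
    "tied")
  expect_equal(mr$tau_curve$mean_tau, 0)
})
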