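# Relabel an integer/character label vector to dense 1..K, keeping the
# order of first appearance.
densify_labels <- function(z) {
  match(z, unique(z))
}

#' Modularity of a partition at resolution gamma
#'
#' Computes
#' \deqn{Q = \frac{1}{2M'} \sum_{i,j} \Big[a_{ij} - \gamma \frac{d_i d_j}{2M'}\Big]\,\delta(z_i, z_j),}
#' where the sum runs over ordered node pairs, \eqn{a_{ij}} is the (possibly
#' weighted) adjacency, \eqn{d_i} the strength of node i, \eqn{M'} the total
#' edge weight, and \eqn{\gamma} the resolution parameter controlling
#' community sizes. Evaluated communitywise in O(M) as
#' \eqn{\sum_c [2 w_c - \gamma (D_c)^2/(2M')]/(2M')} with \eqn{w_c} the
#' within-community edge weight and \eqn{D_c} the community strength sum.
#'
#' The all-in-one partition scores exactly 0 at \eqn{\gamma = 1}; higher is
#' better.
#'
#' @param g An undirected igraph (weights honored).
#' @param z Integer partition vector, one label per node.
#' @param gamma Positive resolution parameter (default 1).
#' @return The modularity score (a real number).
#' @export
modularity_score <- function(g, z, gamma = 1) {
  n <- igraph::vcount(g)
  if (length(z) != n) stop("partition length must equal number of nodes")
  if (length(gamma) != 1 || is.na(gamma) || gamma <= 0) {
    stop("gamma must be a positive real")
  }
  m2 <- 2 * total_weight(g)
  if (m2 == 0) stop("modularity undefined on a graph with no edges")
  z <- densify_labels(z)
  K <- max(z)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- edge_weights(g)
  within <- z[el[, 1]] == z[el[, 2]]
  w_in <- numeric(K)
  if (any(within)) {
    agg <- tapply(w[within], z[el[within, 1]], sum)
    w_in[as.integer(names(agg))] <- agg
  }
  strength <- igraph::strength(g, weights = w)
  D <- numeric(K)
  agg <- tapply(strength, z, sum)
  D[as.integer(names(agg))] <- agg
  sum(2 * w_in) / m2 - gamma * sum((D / m2)^2)
}

#' Detect communities by weighted Louvain modularity maximization
#'
#' Runs the Louvain agglomerative heuristic (local moving plus graph
#' aggregation) honoring edge weights and the resolution parameter. The node
#' processing order inside the heuristic is a seeded pseudo-random shuffle,
#' so distinct seeds reproduce the run-to-run variability of the method while
#' identical `(g, gamma, rng_seed)` always return the identical partition.
#'
#' The returned partition is guaranteed to score at least as high as both
#' trivial partitions (everything in one community; every node its own
#' community) under [modularity_score()] at the same `gamma`; in the measure-
#' zero event the heuristic returns something worse, the better trivial
#' partition is substituted.
#'
#' @param g A non-empty undirected igraph.
#' @param gamma Positive resolution parameter.
#' @param rng_seed Integer seed for the node-shuffle randomness.
#' @return Integer partition vector with dense labels `1..K`.
#' @export
detect_modularity <- function(g, gamma = 1, rng_seed = 1L) {
  if (igraph::vcount(g) == 0) stop("graph has no nodes")
  if (length(gamma) != 1 || is.na(gamma) || gamma <= 0) {
    stop("gamma must be a positive real")
  }
  w <- edge_weights(g)
  z <- withr::with_seed(as.integer(rng_seed), {
    as.integer(igraph::membership(
      igraph::cluster_louvain(g, weights = w, resolution = gamma)))
  })
  z <- densify_labels(z)
  if (total_weight(g) == 0) return(z)
  q <- modularity_score(g, z, gamma)
  n <- igraph::vcount(g)
  q1 <- modularity_score(g, rep(1L, n), gamma)
  qn <- modularity_score(g, seq_len(n), gamma)
  if (q < q1 || q < qn) {
    z <- if (q1 >= qn) rep(1L, n) else seq_len(n)
  }
  z
}

#' Maximum-likelihood Bernoulli block matrix for a partition
#'
#' Under the stochastic block model, each node pair (i, j) carries an edge
#' independently with probability \eqn{\pi_{z_i z_j}}. Given an observed
#' unweighted graph and a partition, the MLE is
#' \eqn{\hat\pi_{kl} = m_{kl} / P_{kl}}: observed edges between blocks k and
#' l over the number of possible pairs (\eqn{n_k n_l} off-diagonal,
#' \eqn{n_k (n_k - 1)/2} within-block). Blocks with zero possible pairs
#' (singleton diagonal) get \eqn{\hat\pi = 0}.
#'
#' @param g An undirected unweighted igraph (all edge weights 1).
#' @param z Integer partition vector.
#' @return A symmetric K x K matrix of edge probabilities.
#' @export
estimate_block_matrix <- function(g, z) {
  if (length(z) != igraph::vcount(g)) stop("partition length mismatch")
  if (any(edge_weights(g) != 1)) {
    stop("Bernoulli block model requires an unweighted graph")
  }
  z <- as.integer(z)
  if (anyNA(z) || any(z < 1)) stop("labels must be positive integers")
  K <- max(z)  # block k keeps the caller's label k, so pi rows line up
  nk <- tabulate(z, K)
  m <- matrix(0, K, K)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) {
    zk <- z[el[, 1]]; zl <- z[el[, 2]]
    for (e in seq_len(nrow(el))) {
      m[zk[e], zl[e]] <- m[zk[e], zl[e]] + 1
      if (zk[e] != zl[e]) m[zl[e], zk[e]] <- m[zl[e], zk[e]] + 1
    }
  }
  pairs <- outer(nk, nk)
  diag(pairs) <- nk * (nk - 1) / 2
  pi_hat <- ifelse(pairs > 0, m / pairs, 0)
  (pi_hat + t(pi_hat)) / 2  # enforce exact symmetry
}

#' Bernoulli stochastic block model log-likelihood
#'
#' Log of the SBM likelihood
#' \eqn{\prod_{i<j} \pi_{z_i z_j}^{a_{ij}} (1 - \pi_{z_i z_j})^{1 - a_{ij}}},
#' evaluated once per unordered node pair (the ordered-pair product over
#' \eqn{i \ne j} with a symmetric \eqn{\pi} is exactly twice this value, so
#' the maximizing partition is unaffected). The convention `0 * log(0) = 0`
#' applies: a \eqn{\pi} entry of exactly 0 or 1 that perfectly matches the
#' data contributes nothing, while one contradicted by an observed (or
#' absent) edge yields `-Inf`.
#'
#' @param g An undirected unweighted igraph.
#' @param z Integer partition vector.
#' @param pi A symmetric K x K matrix of probabilities in `[0, 1]`.
#' @return The log-likelihood, a number `<= 0` (possibly `-Inf`).
#' @export
sbm_log_likelihood <- function(g, z, pi) {
  n <- igraph::vcount(g)
  if (length(z) != n) stop("partition length mismatch")
  if (any(edge_weights(g) != 1)) {
    stop("Bernoulli block model requires an unweighted graph")
  }
  z <- as.integer(z)
  if (anyNA(z) || any(z < 1)) stop("labels must be positive integers")
  K <- max(z)
  if (!is.matrix(pi) || nrow(pi) < K || ncol(pi) < K) {
    stop("pi must be at least K x K for the K blocks of z")
  }
  if (any(pi < 0 | pi > 1)) stop("pi entries must lie in [0, 1]")
  nk <- tabulate(z, K)
  pairs <- outer(nk, nk)
  diag(pairs) <- nk * (nk - 1) / 2
  m <- matrix(0, K, K)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) {
    a <- pmin(z[el[, 1]], z[el[, 2]]); b <- pmax(z[el[, 1]], z[el[, 2]])
    for (e in seq_along(a)) m[a[e], b[e]] <- m[a[e], b[e]] + 1
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  ll <- 0
  for (k in seq_len(K)) for (l in k:K) {
    P <- pairs[k, l]; mk <- m[k, l]; p <- pi[k, l]
    if (P == 0) next
    if (mk > 0) {
      if (p == 0) return(-Inf)
      ll <- ll + mk * log(p)
    }
    if (P - mk > 0) {
      if (p == 1) return(-Inf)
      ll <- ll + (P - mk) * log1p(-p)
    }
  }
  ll
}

#' Number of blocks of a reference partition
#'
#' The block count of the compressed-representation partition, handed to an
#' SBM backend as a fixed number of blocks so full-network inference lives at
#' the same scale ("matched block count").
#'
#' @param z_ref Non-empty integer partition vector.
#' @return Positive integer K.
#' @export
matched_block_count <- function(z_ref) {
  if (!length(z_ref)) stop("partition must be non-empty")
  length(unique(z_ref))
}

#' Select the resolution parameter matched to a reference partition
#'
#' Finds the resolution `gamma` at which full-network Louvain partitions live
#' at the same scale as a reference (typically lifted super-node) partition.
#' For each candidate `gamma`, the full graph is partitioned
#' `runs_per_gamma` times with distinct derived seeds; each partition is
#' turned into a node ranking by the size of the community containing each
#' node (all members of one community share a rank), and Kendall's tau-b
#' between that ranking and the reference's ranking is computed. The gamma
#' with the highest mean tau-b wins; ties go to the smaller gamma. Tau-b is
#' used because community-size rankings are heavily tied; the fully-tied
#' degenerate case (both rankings constant) is defined as 0 with a warning.
#'
#' @param g_full The full (uncompressed) graph.
#' @param z_ref Reference partition over the full node set.
#' @param gammas Candidate resolutions; default 25 log-spaced points in
#'   `[0.05, 2.5]`.
#' @param runs_per_gamma Louvain runs per candidate (default 5).
#' @param rng_seed Master seed; per-run seeds are derived by a counter.
#' @return A list with `gamma_star` and `tau_curve` (data frame of
#'   `gamma`, `mean_tau`).
#' @export
matched_resolution <- function(g_full, z_ref,
                               gammas = exp(seq(log(0.05), log(2.5),
                                                length.out = 25)),
                               runs_per_gamma = 5, rng_seed = 1L) {
  if (!length(gammas)) stop("gamma grid must be non-empty")
  if (length(z_ref) != igraph::vcount(g_full)) {
    stop("reference partition length mismatch")
  }
  ref_rank <- community_size_ranking(z_ref)
  mean_tau <- vapply(seq_along(gammas), function(gi) {
    taus <- vapply(seq_len(runs_per_gamma), function(r) {
      z <- detect_modularity(g_full, gammas[gi],
                             derive_seed(rng_seed, gi * 1000L + r))
      tau_b_ranking(community_size_ranking(z), ref_rank)
    }, numeric(1))
    mean(taus)
  }, numeric(1))
  best <- which(mean_tau == max(mean_tau))
  gamma_star <- min(gammas[best])
  list(gamma_star = gamma_star,
       tau_curve = data.frame(gamma = gammas, mean_tau = mean_tau))
}

# Ascending rank of each node by the size of its community (ties shared).
community_size_ranking <- function(z) {
  z <- densify_labels(z)
  tabulate(z, max(z))[z]
}

tau_b_ranking <- function(x, y) {
  if (length(unique(x)) == 1 && length(unique(y)) == 1) {
    warning("both rankings fully tied; Kendall tau undefined, returning 0")
    return(0)
  }
  tau <- suppressWarnings(stats::cor(x, y, method = "kendall"))
  if (is.na(tau)) {
    warning("Kendall tau undefined (one ranking fully tied); returning 0")
    return(0)
  }
  tau
}

# Deterministic 32-bit seed derivation from a master seed and a counter.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 7919 + as.double(counter) * 104729) %%
               2147483647)
}

#' Resolve a community-detection backend by tag
#'
#' Returns a function `(g, rng_seed) -> partition`. Tag `"louvain"` is
#' weighted Louvain at the given resolution. Tag `"sbm"` is the built-in
#' surrogate for likelihood-based inference: a Louvain partition whose
#' Bernoulli block matrix is then fit by maximum likelihood — full
#' agglomerative SBM samplers can be plugged in as a custom function with
#' the same signature.
#'
#' @param tag `"louvain"`, `"sbm"`, or a function `(g, rng_seed)` returning
#'   a partition, used as-is.
#' @param gamma Resolution handed to the Louvain-based backends.
#' @return A detector function.
#' @export
get_detector <- function(tag, gamma = 1) {
  if (is.function(tag)) return(tag)
  switch(tag,
    louvain = function(g, rng_seed) detect_modularity(g, gamma, rng_seed),
    sbm = function(g, rng_seed) {
      z <- detect_modularity(g, gamma, rng_seed)
      attr(z, "block_matrix") <- if (all(edge_weights(g) == 1)) {
        estimate_block_matrix(g, z)
      }
      z
    },
    stop("unknown detector tag: ", tag)
  )
}
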