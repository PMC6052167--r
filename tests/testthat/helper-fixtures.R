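# Small graph constructors and independent oracles shared across test files.
# All oracles are written against igraph primitives or brute force, never
# against the package's own code paths.

mk_graph <- function(u, v, n = max(c(u, v)), w = rep(1, length(u))) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(u)) {
    g <- igraph::add_edges(g, rbind(u, v), weight = w)
  } else {
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
  }
  igraph::set_vertex_attr(g, "label", value = as.character(seq_len(n)))
}

# Two triangles {1,2,3} and {4,5,6} joined by the bridge 3-4.
g_two_triangles <- function() {
  mk_graph(c(1, 1, 2, 4, 4, 5, 3), c(2, 3, 3, 5, 6, 6, 4))
}

g_path <- function(n) mk_graph(seq_len(n - 1), 2:n)

# Star: center 1, leaves 2..n.
g_star <- function(n) mk_graph(rep(1, n - 1), 2:n)

g_cycle <- function(n) mk_graph(seq_len(n), c(2:n, 1))

random_gnp <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    g <- igraph::set_edge_attr(g, "weight",
                               value = rep(1, igraph::ecount(g)))
    igraph::set_vertex_attr(g, "label", value = as.character(seq_len(n)))
  })
}

# --- independent oracles ---------------------------------------------------

# k-core membership straight from igraph's coreness.
oracle_kcore <- function(g, k) which(igraph::coreness(g) >= k)

# CoreHD by literal restatement: after every removal, rebuild the working
# graph and recompute its 2-core from scratch via coreness; fall back to
# highest degree on the residual graph when the 2-core is empty.
oracle_corehd <- function(g, S) {
  h <- g
  igraph::V(h)$orig <- seq_len(igraph::vcount(g))
  seeds <- integer(S)
  for (s in seq_len(S)) {
    core <- which(igraph::coreness(h) >= 2)
    pick_in <- if (length(core)) {
      sub <- igraph::induced_subgraph(h, core)
      deg <- igraph::degree(sub)
      core[order(-deg, igraph::V(sub)$orig)[1]]
    } else {
      deg <- igraph::degree(h)
      order(-deg, igraph::V(h)$orig)[1]
    }
    seeds[s] <- igraph::V(h)$orig[pick_in]
    h <- igraph::delete_vertices(h, pick_in)
  }
  seeds
}

# Entropy-based NMI oracle: mutual information normalized by the arithmetic
# mean of the marginal entropies, computed from empirical probabilities —
# an independent route to the same quantity as the contingency-table form.
oracle_nmi <- function(a, b) {
  n <- length(a)
  pa <- as.vector(table(a)) / n
  pb <- as.vector(table(b)) / n
  pj <- as.matrix(table(a, b)) / n
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  if (ha + hb == 0) return(1)
  ratio <- pj / outer(pa, pb)
  mi <- sum(pj[pj > 0] * log(ratio[pj > 0]))
  2 * mi / (ha + hb)
}

# Bernoulli SBM log-likelihood by brute force over all unordered pairs.
oracle_sbm_ll <- function(g, z, pi) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  ll <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- pi[z[i], z[j]]
    a <- A[i, j]
    term <- if (a == 1) {
      if (p == 0) return(-Inf) else log(p)
    } else {
      if (p == 1) return(-Inf) else log(1 - p)
    }
    ll <- ll + term
  }
  ll
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_label) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(next_label)) {
      rec(c(labels, l), max(next_label, l + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

# AUC by all-pairs positive/negative comparison with half-credit ties.
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

densify_labels_for_test <- function(z) match(z, unique(z))
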