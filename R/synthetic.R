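#' Planted-partition benchmark graph
#'
#' Splits `n` nodes into `K` near-equal blocks (the first `n %% K` blocks get
#' one extra node) and places an edge independently with probability `p_in`
#' for within-block pairs and `p_out` for cross-block pairs — the Bernoulli
#' stochastic block model with assortative planted structure. No self loops;
#' fully reproducible from the seed.
#'
#' @param n Number of nodes.
#' @param K Number of planted blocks, `K <= n`.
#' @param p_in Within-block edge probability, in `(0, 1]`.
#' @param p_out Cross-block edge probability, in `[0, 1)`; must be `< p_in`.
#' @param rng_seed Integer seed.
#' @return A list with `graph` (igraph), `truth` (planted partition,
#'   length n) and `params`.
#' @export
planted_partition_graph <- function(n, K, p_in, p_out, rng_seed = 1L) {
  if (K < 1 || K > n) stop("need 1 <= K <= n")
  if (!(p_in > 0 && p_in <= 1)) stop("p_in must lie in (0, 1]")
  if (!(p_out >= 0 && p_out < 1)) stop("p_out must lie in [0, 1)")
  if (p_out >= p_in) stop("assortative fixture requires p_in > p_out")
  sizes <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  truth <- rep(seq_len(K), sizes)
  blocks <- split(seq_len(n), truth)
  edges <- withr::with_seed(as.integer(rng_seed), {
    out <- list()
    for (a in seq_len(K)) for (b in a:K) {
      if (a == b) {
        ids <- blocks[[a]]
        if (length(ids) < 2) next
        pr <- utils::combn(ids, 2)
        keep <- stats::runif(ncol(pr)) < p_in
      } else {
        if (p_out == 0) next
        pr <- rbind(rep(blocks[[a]], each = length(blocks[[b]])),
                    rep(blocks[[b]], times = length(blocks[[a]])))
        keep <- stats::runif(ncol(pr)) < p_out
      }
      out[[length(out) + 1L]] <- pr[, keep, drop = FALSE]
    }
    do.call(cbind, out)
  })
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && ncol(edges)) {
    g <- igraph::add_edges(g, edges, weight = rep(1, ncol(edges)))
  } else {
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
  }
  g <- igraph::set_vertex_attr(g, "label", value = as.character(seq_len(n)))
  list(graph = g, truth = truth,
       params = list(n = n, K = K, p_in = p_in, p_out = p_out,
                     rng_seed = rng_seed))
}

#' Ring of cliques benchmark graph
#'
#' `k` cliques of `c` nodes each; clique j is joined to clique `j + 1 (mod
#' k)` by exactly one bridge edge between the lowest-id node of each clique.
#' Deterministic; the edge count is exactly `k * c * (c - 1) / 2 + k`. The
#' planted truth is clique membership — the textbook fixture on which
#' community structure is unambiguous and local-agreement prediction is
#' perfect.
#'
#' @param k Number of cliques, `>= 3`.
#' @param c Clique size, `>= 3`.
#' @return A list with `graph`, `truth`, and `params`, as in
#'   [planted_partition_graph()].
#' @export
ring_of_cliques <- function(k, c) {
  if (k < 3) stop("need k >= 3 cliques")
  if (c < 3) stop("need clique size c >= 3")
  n <- k * c
  truth <- rep(seq_len(k), each = c)
  blocks <- split(seq_len(n), truth)
  within <- do.call(cbind, lapply(blocks, function(ids) utils::combn(ids, 2)))
  anchors <- vapply(blocks, min, 1L)
  bridges <- rbind(anchors, anchors[c(seq_len(k)[-1], 1L)])
  edges <- cbind(within, bridges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, edges, weight = rep(1, ncol(edges)))
  g <- igraph::set_vertex_attr(g, "label", value = as.character(seq_len(n)))
  list(graph = g, truth = truth, params = list(k = k, c = c))
}
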