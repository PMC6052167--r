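#' Select super-node seeds by CoreHD
#'
#' CoreHD picks, at each step, the highest-degree node of the 2-core of the
#' current working graph, where degree is measured within the induced
#' subgraph of the 2-core. The chosen node and its incident edges are removed
#' and the 2-core is recomputed before the next pick. The procedure comes
#' from network decycling/dismantling, where deleting core hubs rapidly
#' decomposes the graph; here it yields seeds that are central, collapse the
#' network quickly, and end up well separated.
#'
#' Ties are broken toward the lowest node id. If the 2-core empties before
#' `S` seeds are found, selection continues by highest degree on the residual
#' working graph (same tie rule; isolated nodes are only picked once no
#' positive-degree node remains), so `S` seeds always exist. The whole
#' procedure is deterministic, and `corehd_seeds(g, S1)` is a prefix of
#' `corehd_seeds(g, S2)` for `S1 <= S2`.
#'
#' @param g An undirected igraph.
#' @param S Number of seeds, `1 <= S <= N`.
#' @return Integer vector of `S` distinct node ids in selection order.
#' @seealso [highest_degree_seeds()] for the one-shot baseline.
#' @export
corehd_seeds <- function(g, S) {
  n <- igraph::vcount(g)
  if (length(S) != 1 || is.na(S) || S < 1) stop("S must be a positive integer")
  if (S > n) stop("S (", S, ") exceeds number of nodes (", n, ")")
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  alive <- rep(TRUE, n)
  deg <- vapply(adj, length, 1L)  # degree in the working graph
  seeds <- integer(S)
  for (s in seq_len(S)) {
    core <- two_core_alive(adj, alive, deg)
    pick <- if (any(core)) {
      # degree within the induced 2-core subgraph
      cd <- integer(n)
      idx <- which(core)
      for (v in idx) cd[v] <- sum(core[adj[[v]]] & alive[adj[[v]]])
      cd[!core] <- -1L
      which.max(cd)  # first maximum = lowest id
    } else {
      d <- deg
      d[!alive] <- -1L
      which.max(d)
    }
    seeds[s] <- pick
    alive[pick] <- FALSE
    nb <- adj[[pick]]
    nb <- nb[alive[nb]]
    deg[nb] <- deg[nb] - 1L
    deg[pick] <- 0L
  }
  seeds
}

# 2-core of the alive subgraph by iterated pruning; returns a logical mask.
# deg must be the degree vector of the alive-induced subgraph (not modified).
two_core_alive <- function(adj, alive, deg) {
  core <- alive
  d <- deg
  repeat {
    drop <- which(core & d < 2L)
    if (!length(drop)) break
    core[drop] <- FALSE
    for (v in drop) {
      nb <- adj[[v]]
      nb <- nb[core[nb]]
      d[nb] <- d[nb] - 1L
    }
    d[drop] <- 0L
  }
  core
}

#' Select seeds by highest degree
#'
#' The naive baseline: the `S` nodes of highest degree in `g`, ranked by
#' descending degree with ties broken by ascending node id. No removal or
#' recomputation takes place.
#'
#' @inheritParams corehd_seeds
#' @return Integer vector of `S` node ids in selection order.
#' @export
highest_degree_seeds <- function(g, S) {
  n <- igraph::vcount(g)
  if (length(S) != 1 || is.na(S) || S < 1) stop("S must be a positive integer")
  if (S > n) stop("S (", S, ") exceeds number of nodes (", n, ")")
  deg <- igraph::degree(g)
  order(-deg, seq_len(n))[seq_len(S)]
}

#' Jaccard similarity between two seed sets
#'
#' `|a intersect b| / |a union b|`, treating the ordered seed lists as sets.
#' Used to compare seed-selection strategies.
#'
#' @param a,b Non-empty integer vectors of node ids.
#' @return A number in `[0, 1]`.
#' @export
seed_jaccard <- function(a, b) {
  if (!length(a) || !length(b)) stop("seed sets must be non-empty")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Read a seed list from a file
#'
#' One node label per line, selection order top to bottom. Labels are matched
#' against the graph's `label` vertex attribute, so externally computed seed
#' lists (e.g. from other compression methods) can be plugged in anywhere a
#' seed set is required.
#'
#' @param path Path to the seed file.
#' @param g The graph the seeds refer to.
#' @return Integer vector of internal node ids in file order.
#' @export
read_seed_file <- function(path, g) {
  if (!file.exists(path)) stop("seed file not found: ", path)
  lab <- trimws(readLines(path, warn = FALSE))
  lab <- lab[nzchar(lab) & !startsWith(lab, "#")]
  ids <- match(lab, node_labels(g))
  if (anyNA(ids)) stop("seed label not in graph: ", lab[which(is.na(ids))[1]])
  if (anyDuplicated(ids)) stop("duplicate seed in file: ", path)
  as.integer(ids)
}
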