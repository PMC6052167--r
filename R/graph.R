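#' Read an undirected graph from a whitespace-delimited edge list
#'
#' Parses files with one edge per line: two node labels, optionally followed
#' by a positive numeric weight. Lines starting with `#` and blank lines are
#' ignored. Node labels may be arbitrary strings; they are densified to
#' internal ids `1..N` in order of first appearance, and the original labels
#' are kept as the `label` vertex attribute so partitions and seed sets can
#' be written back in the input's vocabulary.
#'
#' Duplicate unordered edges are collapsed (weights summed when `weighted`,
#' deduplicated otherwise) and self loops are dropped with a message giving
#' the count. Unweighted edges get weight 1.
#'
#' @param path Path to the edge-list file.
#' @param weighted Logical; if `TRUE` each line must carry a third numeric
#'   column with a strictly positive weight.
#' @return An undirected [igraph::igraph] with vertex attribute `label` and
#'   edge attribute `weight`.
#' @export
read_edgelist <- function(path, weighted = FALSE) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  toks <- strsplit(trimws(lines), "\\s+")
  want <- if (weighted) 3L else 2L
  bad <- which(vapply(toks, length, 1L) != want)
  if (length(bad)) {
    stop("malformed edge list line ", lineno[bad[1]], ": expected ", want,
         " whitespace-separated fields, got '", lines[bad[1]], "'")
  }
  u <- vapply(toks, `[[`, "", 1L)
  v <- vapply(toks, `[[`, "", 2L)
  w <- if (weighted) {
    wv <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
    if (anyNA(wv)) {
      stop("malformed edge list line ", lineno[which(is.na(wv))[1]],
           ": non-numeric weight")
    }
    if (any(wv <= 0)) {
      stop("invalid weight on line ", lineno[which(wv <= 0)[1]],
           ": weights must be strictly positive")
    }
    wv
  } else {
    rep(1, length(u))
  }
  labels <- unique(c(rbind(u, v)))  # first-appearance order across (u, v) pairs
  ui <- match(u, labels)
  vi <- match(v, labels)
  make_graph_from_pairs(ui, vi, w, n = length(labels), labels = labels,
                        sum_duplicates = weighted)
}

#' Write a graph as a whitespace-delimited edge list
#'
#' Emits one line per unordered edge, endpoints in ascending internal id
#' order within a line and lines sorted by (first, second) endpoint, so
#' output is deterministic. Original labels (the `label` vertex attribute)
#' are written when present.
#'
#' @param g An undirected igraph.
#' @param path Output file path.
#' @param weighted Logical; write the weight as a third column.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path, weighted = FALSE) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) {
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    ord <- order(el[, 1], el[, 2])
    el <- el[ord, , drop = FALSE]
    lab <- node_labels(g)
    out <- paste(lab[el[, 1]], lab[el[, 2]])
    if (weighted) out <- paste(out, format(edge_weights(g)[ord], trim = TRUE))
  } else {
    out <- character(0)
  }
  writeLines(out, path)
  invisible(path)
}

# Construct a simple undirected weighted graph from parallel endpoint vectors,
# dropping self loops (with a message) and collapsing duplicate unordered
# pairs. Internal workhorse shared by the reader and the generators.
make_graph_from_pairs <- function(ui, vi, w, n, labels = NULL,
                                  sum_duplicates = FALSE) {
  loops <- ui == vi
  if (any(loops)) {
    message("dropped ", sum(loops), " self loop(s)")
    ui <- ui[!loops]; vi <- vi[!loops]; w <- w[!loops]
  }
  a <- pmin(ui, vi); b <- pmax(ui, vi)
  key <- paste(a, b)
  if (anyDuplicated(key)) {
    w <- if (sum_duplicates) {
      as.numeric(tapply(w, key, sum)[unique(key)])
    } else {
      as.numeric(tapply(w, key, `[`, 1L)[unique(key)])
    }
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(a)) {
    g <- igraph::add_edges(g, rbind(a, b), weight = w)
  } else {
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
  }
  if (is.null(labels)) labels <- as.character(seq_len(n))
  igraph::set_vertex_attr(g, "label", value = labels)
}

node_labels <- function(g) {
  lab <- igraph::vertex_attr(g, "label")
  if (is.null(lab)) as.character(seq_len(igraph::vcount(g))) else lab
}

edge_weights <- function(g) {
  w <- igraph::edge_attr(g, "weight")
  if (is.null(w)) rep(1, igraph::ecount(g)) else w
}

#' Total edge weight of a graph
#'
#' For an unweighted graph this is the edge count M; for a weighted graph it
#' is the sum of edge weights (the M' entering the modularity normalisation).
#'
#' @param g An igraph.
#' @return A non-negative number.
#' @export
total_weight <- function(g) sum(edge_weights(g))

check_nodes <- function(g, ids, what = "node id") {
  n <- igraph::vcount(g)
  ids <- as.integer(ids)
  if (length(ids) == 0 || anyNA(ids) || any(ids < 1L) || any(ids > n)) {
    stop(what, " out of range 1..", n)
  }
  ids
}

#' Extract the k-core of a graph
#'
#' Returns the maximal set of nodes such that every node has degree >= k
#' within the induced subgraph, computed by iterated pruning of nodes with
#' degree < k until a fixpoint. Degree counts edges, ignoring weights. The
#' result may be empty (e.g. the 2-core of any forest) and may span several
#' connected components.
#'
#' @param g An undirected igraph.
#' @param k Positive integer core order.
#' @return Integer vector of node ids (ascending), possibly empty.
#' @export
k_core <- function(g, k) {
  if (length(k) != 1 || is.na(k) || k < 1) stop("k must be a positive integer")
  alive <- rep(TRUE, igraph::vcount(g))
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  repeat {
    drop <- which(alive & deg < k)
    if (!length(drop)) break
    alive[drop] <- FALSE
    for (v in drop) {
      nb <- as.integer(adj[[v]])
      nb <- nb[alive[nb]]
      deg[nb] <- deg[nb] - 1L
    }
    deg[drop] <- 0L
  }
  which(alive)
}

#' Nodes within a bounded-radius neighborhood
#'
#' All nodes at shortest-path distance between 1 and `o` from node `i`
#' (breadth-first; `i` itself excluded). Edge weights are ignored: distance
#' is hop count.
#'
#' @param g An undirected igraph.
#' @param i Node id.
#' @param o Positive integer neighborhood order.
#' @return Integer vector of node ids (ascending), possibly empty.
#' @export
neighborhood_within <- function(g, i, o) {
  i <- check_nodes(g, i)
  if (length(i) != 1) stop("i must be a single node id")
  if (length(o) != 1 || is.na(o) || o < 1) stop("o must be a positive integer")
  nb <- igraph::ego(g, order = o, nodes = i, mode = "all", mindist = 1)[[1]]
  sort(as.integer(nb))
}
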