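#' Compress a network and detect communities end to end
#'
#' The full pipeline: select seeds, grow super nodes, build the weighted
#' compressed network, detect communities on it, and lift the result back to
#' the original nodes. Optionally also detects on the full graph (same
#' detector, fresh derived seed) and reports the agreement and quality
#' metrics: `NMI(z^Full, z^SN)`, under-segmentation error, modularity of
#' both partitions, and coverage (fraction of nodes assigned to a super
#' node).
#'
#' @param g An undirected igraph.
#' @param S Number of super nodes.
#' @param o_max Growth order (default 6).
#' @param seed_strategy `"corehd"` (default), `"degree"`, or `"file"`
#'   (requires `seed_file`); ignored when `seeds` is given directly.
#' @param seeds Optional explicit seed-id vector (external seeders plug in
#'   here).
#' @param seed_file Path to a seed list file (one label per line), used when
#'   `seed_strategy = "file"`.
#' @param detector Backend tag or function, see [get_detector()].
#' @param gamma Resolution parameter (default 1).
#' @param rng_seed Master seed; detector seeds are derived from it.
#' @param detect_full Also run the detector on the full graph (default TRUE).
#' @param exclude_periphery Exclude the periphery super node from the
#'   under-segmentation error.
#' @return A `supernode_run`: list with `z_sn` (lifted partition), `z_full`
#'   (or NULL), `assignment`, `network`, `metrics` (named numeric vector)
#'   and `config`.
#' @export
compress_and_detect <- function(g, S, o_max = 6,
                                seed_strategy = c("corehd", "degree", "file"),
                                seeds = NULL, seed_file = NULL,
                                detector = "louvain", gamma = 1,
                                rng_seed = 1L, detect_full = TRUE,
                                exclude_periphery = FALSE) {
  seed_strategy <- match.arg(seed_strategy)
  if (is.null(seeds)) {
    seeds <- switch(seed_strategy,
      corehd = corehd_seeds(g, S),
      degree = highest_degree_seeds(g, S),
      file = {
        if (is.null(seed_file)) stop("seed_strategy='file' needs seed_file")
        read_seed_file(seed_file, g)
      })
  }
  s <- grow_supernodes(g, seeds, o_max)
  snw <- build_supernode_network(g, s)
  det <- get_detector(detector, gamma)
  z_sn <- lift_partition(s, det(snw$graph, derive_seed(rng_seed, 1L)))
  z_full <- NULL
  metrics <- c(coverage = 1 - length(snw$periphery) / igraph::vcount(g),
               modularity_sn = modularity_score(g, z_sn, gamma),
               k_sn = matched_block_count(z_sn))
  if (detect_full) {
    z_full <- det(g, derive_seed(rng_seed, 2L))
    metrics <- c(metrics,
                 nmi = nmi(z_full, z_sn),
                 u = under_segmentation_error(snw, z_full,
                                              exclude_periphery),
                 modularity_full = modularity_score(g, z_full, gamma),
                 k_full = matched_block_count(z_full))
  }
  structure(list(z_sn = z_sn, z_full = z_full, assignment = s,
                 network = snw, metrics = metrics,
                 config = list(S = length(seeds), o_max = o_max,
                               seed_strategy = seed_strategy,
                               detector = if (is.character(detector))
                                 detector else "custom",
                               gamma = gamma, rng_seed = rng_seed,
                               exclude_periphery = exclude_periphery)),
            class = "supernode_run")
}

#' @export
print.supernode_run <- function(x, ...) {
  cfg <- x$config
  cat("Super-node compression run: S = ", cfg$S, ", o_max = ", cfg$o_max,
      ", seeds = ", cfg$seed_strategy, ", detector = ", cfg$detector,
      " (gamma = ", cfg$gamma, ", seed = ", cfg$rng_seed, ")\n", sep = "")
  cat("  lifted partition: ", matched_block_count(x$z_sn),
      " communities over ", length(x$z_sn), " nodes\n", sep = "")
  m <- x$metrics
  cat("  ", paste(sprintf("%s = %.4g", names(m), m), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a partition to a two-column file
#'
#' One line per node: original node label and community id, in node order.
#'
#' @param z Integer partition vector.
#' @param g The graph the partition refers to (for node labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(z, g, path) {
  if (length(z) != igraph::vcount(g)) stop("partition length mismatch")
  writeLines(paste(node_labels(g), z), path)
  invisible(path)
}

#' Read a partition from a two-column file
#'
#' @param path Path to a "node_id community_id" file.
#' @param g The graph the partition refers to.
#' @return Integer partition vector in internal node order, labels
#'   densified.
#' @export
read_partition <- function(path, g) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  if (any(vapply(toks, length, 1L) != 2L)) stop("malformed partition file")
  ids <- match(vapply(toks, `[[`, "", 1L), node_labels(g))
  if (anyNA(ids)) stop("partition file names a node not in the graph")
  z <- integer(igraph::vcount(g))
  z[ids] <- as.integer(vapply(toks, `[[`, "", 2L))
  if (length(ids) != igraph::vcount(g)) stop("partition file misses nodes")
  densify_labels(z)
}

#' Write a super-node assignment to a two-column file
#'
#' One line per original node: node label and super-node index, with
#' periphery written as -1.
#'
#' @param s A `supernode_assignment`.
#' @param g The parent graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(s, g, path) {
  a <- s$assignment
  a[is.na(a)] <- -1L
  writeLines(paste(node_labels(g), a), path)
  invisible(path)
}
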