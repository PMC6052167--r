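#' Per-node community probabilities from neighborhood composition
#'
#' For every node i, considers all nodes within shortest-path distance `o`
#' (excluding i itself) and scores each community k by the fraction of those
#' neighbors assigned to k under `z`. Rows of nodes with at least one
#' neighbor within order `o` sum to 1; nodes isolated within order `o` get
#' an all-zero row and are flagged in the `scorable` attribute.
#'
#' @param g An undirected igraph.
#' @param z Integer partition vector over the nodes of `g`.
#' @param o Positive integer neighborhood order (cumulative: distance <= o).
#' @return An n x K numeric matrix with attribute `scorable` (logical
#'   vector) and `o`.
#' @export
neighbor_community_scores <- function(g, z, o = 1) {
  n <- igraph::vcount(g)
  if (length(z) != n) stop("partition length must equal number of nodes")
  if (length(o) != 1 || is.na(o) || o < 1) stop("o must be a positive integer")
  z <- densify_labels(z)
  K <- max(z)
  nb <- igraph::ego(g, order = o, mode = "all", mindist = 1)
  scores <- matrix(0, n, K)
  scorable <- logical(n)
  for (i in seq_len(n)) {
    ids <- as.integer(nb[[i]])
    if (!length(ids)) next
    scorable[i] <- TRUE
    scores[i, ] <- tabulate(z[ids], K) / length(ids)
  }
  structure(scores, scorable = scorable, o = o)
}

# Rank-statistic (Mann-Whitney) AUC with midrank tie handling; equivalent to
# trapezoidal integration of the ROC over all distinct score thresholds.
rank_auc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Minimum per-community AUC of neighborhood-based membership prediction
#'
#' The local-agreement summary: for each community k of `z`, a binary
#' classifier predicts membership of each node in k from the fraction of its
#' order-`o` neighbors in k (see [neighbor_community_scores()]); sweeping
#' the probability threshold over all distinct score values traces the ROC,
#' whose area is computed by the rank statistic with midrank tie handling.
#' The minimum AUC across communities is returned — a high value means even
#' the worst-predicted community agrees with local connectivity.
#'
#' Nodes isolated within order `o` are excluded from scoring; the fraction
#' of scorable nodes is attached as the `coverage` attribute. A community
#' with no positive scorable node is skipped with a warning.
#'
#' @inheritParams neighbor_community_scores
#' @return The minimum AUC, in `[0, 1]`, with attributes `per_community`
#'   and `coverage`.
#' @export
min_community_auc <- function(g, z, o = 1) {
  z <- densify_labels(z)
  K <- max(z)
  if (K < 2) stop("need at least 2 communities for the prediction task")
  scores <- neighbor_community_scores(g, z, o)
  ok <- attr(scores, "scorable")
  aucs <- vapply(seq_len(K), function(k) {
    rank_auc(scores[ok, k], z[ok] == k)
  }, numeric(1))
  if (anyNA(aucs)) {
    warning(sum(is.na(aucs)),
            " community(ies) with no scorable positive node skipped")
  }
  structure(min(aucs, na.rm = TRUE), per_community = aucs,
            coverage = mean(ok))
}

#' Super-node quality as a function of the compression level
#'
#' Runs the full pipeline (CoreHD seeds, growth, compressed network,
#' detection, lift) for each requested number of super nodes `S` and each
#' replicate, alongside detection on the full graph, and records
#' `NMI(z^Full, z^SN)` and the under-segmentation error. Seed selection and
#' growth are deterministic, so replicate-to-replicate variation comes from
#' the detector seeds, which are derived from `rng_seed` by a counter and
#' recorded in every row.
#'
#' @param g An undirected igraph.
#' @param S_values Numbers of super nodes to profile.
#' @param replicates Replicates per S (default 5).
#' @param detector Backend tag or function, see [get_detector()].
#' @param o_max Growth order (default 6).
#' @param gamma Resolution for the Louvain-based detectors.
#' @param rng_seed Master seed.
#' @param truth Optional reference partition; when supplied, NMI of the
#'   lifted partition against it is recorded as metric `nmi_truth`.
#' @return A `supernode_experiment`: list with `records` (tidy data frame:
#'   S, replicate, method, metric, value, seed) and `summary` (mean and sd
#'   per S and metric).
#' @export
quality_curve <- function(g, S_values, replicates = 5, detector = "louvain",
                          o_max = 6, gamma = 1, rng_seed = 1L, truth = NULL) {
  if (!length(S_values)) stop("S_values must be non-empty")
  n <- igraph::vcount(g)
  if (any(S_values >= n)) stop("every S must be < number of nodes")
  if (replicates < 1) stop("replicates must be a positive integer")
  det <- get_detector(detector, gamma)
  tag <- if (is.character(detector)) detector else "custom"
  rows <- list()
  for (si in seq_along(S_values)) {
    S <- S_values[si]
    seeds <- corehd_seeds(g, S)
    s <- grow_supernodes(g, seeds, o_max)
    snw <- build_supernode_network(g, s)
    for (r in seq_len(replicates)) {
      seed_sn <- derive_seed(rng_seed, si * 10000L + 2L * r)
      seed_full <- derive_seed(rng_seed, si * 10000L + 2L * r + 1L)
      z_sn <- lift_partition(s, det(snw$graph, seed_sn))
      z_full <- det(g, seed_full)
      vals <- c(nmi = nmi(z_full, z_sn),
                u = under_segmentation_error(snw, z_full))
      if (!is.null(truth)) vals <- c(vals, nmi_truth = nmi(truth, z_sn))
      rows[[length(rows) + 1L]] <- data.frame(
        S = S, replicate = r, method = tag, metric = names(vals),
        value = unname(vals), seed = seed_sn, row.names = NULL)
    }
  }
  records <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ S + metric, records,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(S = agg$S, metric = agg$metric,
                        mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  structure(list(records = records, summary = summary, rng_seed = rng_seed),
            class = "supernode_experiment")
}

#' @export
print.supernode_experiment <- function(x, ...) {
  cat("Super-node experiment (", nrow(x$records), " measurements)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run-to-run partition variability on a chosen representation
#'
#' Produces `runs` partitions per detector on either the full graph or a
#' compressed representation (lifted back to the original nodes), then
#' records the pairwise NMI within each detector and across each detector
#' pair — the three comparison types used to judge whether compression
#' stabilizes stochastic detection output.
#'
#' @param g An undirected igraph.
#' @param representation `"full"` or `"supernode"`.
#' @param S Number of super nodes (required when `representation =
#'   "supernode"`).
#' @param detectors Character vector of backend tags (or list of functions).
#' @param runs Partitions per detector (>= 2).
#' @param o_max,gamma,rng_seed As in [quality_curve()].
#' @return A `supernode_experiment` whose records hold one row per partition
#'   pair, with `method` naming the comparison (`"louvain|louvain"` etc.).
#' @export
variability_matrix <- function(g, representation = c("full", "supernode"),
                               S = NULL, detectors = "louvain", runs = 10,
                               o_max = 6, gamma = 1, rng_seed = 1L) {
  representation <- match.arg(representation)
  if (runs < 2) stop("runs must be >= 2")
  if (representation == "supernode") {
    if (is.null(S)) stop("S is required for the supernode representation")
    s <- grow_supernodes(g, corehd_seeds(g, S), o_max)
    snw <- build_supernode_network(g, s)
  }
  tags <- if (is.list(detectors)) {
    nm <- names(detectors)
    if (is.null(nm)) paste0("detector", seq_along(detectors)) else nm
  } else {
    detectors
  }
  parts <- list()
  for (di in seq_along(tags)) {
    det <- get_detector(if (is.list(detectors)) detectors[[di]]
                        else detectors[di], gamma)
    parts[[tags[di]]] <- lapply(seq_len(runs), function(r) {
      sd <- derive_seed(rng_seed, di * 100000L + r)
      if (representation == "supernode") {
        lift_partition(s, det(snw$graph, sd))
      } else {
        det(g, sd)
      }
    })
  }
  rows <- list()
  for (di in seq_along(tags)) for (dj in di:length(tags)) {
    pi_ <- parts[[di]]; pj <- parts[[dj]]
    cmp <- paste(tags[di], tags[dj], sep = "|")
    if (di == dj) {
      for (a in seq_len(runs - 1)) for (b in (a + 1):runs) {
        rows[[length(rows) + 1L]] <- data.frame(
          S = if (representation == "supernode") S else NA_integer_,
          replicate = paste(a, b, sep = "-"), method = cmp, metric = "nmi",
          value = nmi(pi_[[a]], pj[[b]]), seed = rng_seed)
      }
    } else {
      for (a in seq_len(runs)) for (b in seq_len(runs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          S = if (representation == "supernode") S else NA_integer_,
          replicate = paste(a, b, sep = "-"), method = cmp, metric = "nmi",
          value = nmi(pi_[[a]], pj[[b]]), seed = rng_seed)
      }
    }
  }
  records <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ method, records,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(S = if (representation == "supernode") S else
                          NA_integer_,
                        metric = paste0("pairwise_nmi[", agg$method, "]"),
                        mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  structure(list(records = records, summary = summary, rng_seed = rng_seed),
            class = "supernode_experiment")
}
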