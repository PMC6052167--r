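#' Contingency table between two partitions
#'
#' `counts[i, j]` is the number of nodes carrying label i in `zA` and label j
#' in `zB`. Rows and columns follow the dense label order of each partition.
#'
#' @param zA,zB Equal-length partition vectors.
#' @return An integer matrix with `dimnames` giving the original labels.
#' @export
contingency_table <- function(zA, zB) {
  if (length(zA) != length(zB)) stop("partitions must have equal length")
  table(zA, zB, dnn = NULL)
}

#' Normalized mutual information between two partitions
#'
#' For partitions with contingency table \eqn{N_{ij}}, row sums
#' \eqn{N_{i.}}, column sums \eqn{N_{.j}} and total \eqn{N},
#' \deqn{\mathrm{NMI} = \frac{-2 \sum_{ij} N_{ij} \log\frac{N_{ij} N}{N_{i.} N_{.j}}}
#'                          {\sum_i N_{i.} \log\frac{N_{i.}}{N} + \sum_j N_{.j} \log\frac{N_{.j}}{N}}.}
#' This is mutual information normalized by the arithmetic mean of the two
#' label entropies; 1 means identical up to relabeling, 0 means independent.
#' Terms with \eqn{N_{ij} = 0} contribute 0; the natural logarithm is used
#' (the base cancels). When both partitions are a single community the
#' denominator vanishes; that degenerate case returns 1 (two identical
#' trivial partitions). One trivial and one non-trivial partition yields 0
#' through the formula itself.
#'
#' @param zA,zB Equal-length partition vectors.
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(zA, zB) {
  if (length(zA) != length(zB)) stop("partitions must have equal length")
  if (!length(zA)) stop("partitions must be non-empty")
  tab <- as.matrix(contingency_table(zA, zB))
  n <- sum(tab)
  ri <- rowSums(tab)
  cj <- colSums(tab)
  den <- sum(ri * log(ri / n)) + sum(cj * log(cj / n))
  if (den == 0) return(1)
  pos <- tab > 0
  num <- -2 * sum(tab[pos] * log(tab[pos] * n /
                                   (outer(ri, cj)[pos])))
  num / den
}

#' Under-segmentation error of a super-node cover
#'
#' Quantifies how much super nodes bleed across community boundaries:
#' \deqn{U = \frac{1}{K} \sum_{k_i} \frac{\big[\sum_{s_j : s_j \cap k_i \ne \emptyset} |s_j|\big] - |k_i|}{|k_i|},}
#' averaging, over the communities \eqn{k_i} of a full-network partition,
#' the excess size of the union of all super nodes touching each community,
#' relative to the community's size. `U = 0` exactly when every super node
#' is contained within a single community; any straddling super node makes
#' it strictly positive.
#'
#' By default the periphery (unassigned nodes) participates as one extra
#' super node; set `exclude_periphery = TRUE` to leave those nodes out of
#' the error entirely.
#'
#' @param s A `supernode_assignment` or `supernode_network`, or a plain list
#'   of integer node-id vectors (the membership sets).
#' @param z_full Partition of the original nodes (full-network communities).
#' @param exclude_periphery Logical; drop the periphery super node.
#' @return A non-negative number.
#' @export
under_segmentation_error <- function(s, z_full, exclude_periphery = FALSE) {
  members <- membership_sets(s, exclude_periphery)
  z_full <- densify_labels(z_full)
  K <- max(z_full)
  sizes <- tabulate(z_full, K)
  if (any(sizes == 0)) stop("empty community in z_full")
  sn_size <- vapply(members, length, 1L)
  # communities touched by each super node
  excess <- numeric(K)
  for (j in seq_along(members)) {
    touched <- unique(z_full[members[[j]]])
    excess[touched] <- excess[touched] + sn_size[j]
  }
  mean((excess - sizes) / sizes)
}

membership_sets <- function(s, exclude_periphery = FALSE) {
  if (inherits(s, "supernode_network")) {
    members <- s$membership
    periphery <- s$periphery
  } else if (inherits(s, "supernode_assignment")) {
    members <- split(which(!is.na(s$assignment)),
                     factor(s$assignment[!is.na(s$assignment)],
                            levels = seq_along(s$seed_of)))
    periphery <- which(is.na(s$assignment))
  } else if (is.list(s)) {
    members <- s
    periphery <- integer(0)
  } else {
    stop("s must be a supernode assignment, network, or list of node sets")
  }
  members <- members[vapply(members, length, 1L) > 0]
  if (!exclude_periphery && length(periphery)) {
    members <- c(members, list(periphery))
  }
  members
}

#' Permutation baseline for NMI
#'
#' Estimates the NMI expected by chance between a full-network partition and
#' a compressed-representation partition: the node-to-label mapping of
#' `z_sn` is uniformly shuffled `n_perm` times (community sizes preserved)
#' and the NMI against `z_full` recomputed each time. On the networks this
#' method targets the baseline sits near 0, an order of magnitude below any
#' meaningful agreement.
#'
#' @param z_full,z_sn Equal-length partition vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param rng_seed Integer seed.
#' @return A list with `mean` and `sd` of the permuted NMI values.
#' @export
permutation_nmi_baseline <- function(z_full, z_sn, n_perm = 1000,
                                     rng_seed = 1L) {
  if (length(z_full) != length(z_sn)) stop("partitions must have equal length")
  if (length(n_perm) != 1 || is.na(n_perm) || n_perm < 1) {
    stop("n_perm must be a positive integer")
  }
  vals <- withr::with_seed(as.integer(rng_seed), {
    vapply(seq_len(n_perm), function(i) nmi(z_full, sample(z_sn)), numeric(1))
  })
  list(mean = mean(vals), sd = stats::sd(vals))
}
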