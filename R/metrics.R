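#' Contingency table of two partitions
#'
#' The r x k matrix of co-membership counts \eqn{n_{ij} = |C_i \cap T_j|}
#' underlying all extrinsic cluster evaluation metrics. Both partitions must
#' cover the identical node set.
#'
#' @param p1,p2 `partition`s on the same node set.
#' @return An integer matrix with rows indexed by `p1`'s communities and
#'   columns by `p2`'s (label order = order of first appearance).
#' @export
#' @examples
#' p1 <- partition(c(a = 1, b = 1, c = 2, d = 2, e = 3, f = 3))
#' p2 <- partition(c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2))
#' contingency_table(p1, p2)
contingency_table <- function(p1, p2) {
  lab <- aligned_labels(p1, p2)
  r <- max(lab[, 1]); k <- max(lab[, 2])
  matrix(tabulate((lab[, 2] - 1L) * r + lab[, 1], nbins = r * k), r, k)
}

# one-directional purity of `system` against `truth` (Eq-style max-overlap)
purity_one_way <- function(cont) sum(apply(cont, 1, max)) / sum(cont)

#' Two-way harmonic-mean purity
#'
#' Purity of a clustering against a reference is the fraction of nodes
#' falling in their cluster's best-matching reference community. Since no
#' ground truth exists when comparing two subjects, purity is computed both
#' ways (each partition in turn playing the reference role) and the two
#' values combined by their harmonic mean, giving a symmetric similarity in
#' \[0, 1\].
#'
#' @param p1,p2 `partition`s on the same node set.
#' @return Similarity in \[0, 1\]; 1 for identical partitions.
#' @export
purity_harmonic <- function(p1, p2) {
  cont <- contingency_table(p1, p2)
  u <- purity_one_way(cont)
  v <- purity_one_way(t(cont))
  if (u + v == 0) return(0)
  2 * u * v / (u + v)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the two community labelings under plug-in
#' probabilities, normalized by the average of the two entropies so the
#' value lies in \[0, 1\]. Natural logarithms are used throughout (the
#' normalization makes the result base-invariant as long as the base is
#' consistent). Zero-count cells contribute 0 by the continuity convention
#' `0 log 0 = 0`.
#'
#' Degenerate cases follow the standard clustering-comparison convention:
#' if both partitions are the trivial all-in-one clustering (both entropies
#' zero) the partitions are identical and NMI is 1; if exactly one entropy
#' is zero, NMI is 0.
#'
#' @param p1,p2 `partition`s on the same node set.
#' @return Similarity in \[0, 1\].
#' @export
nmi <- function(p1, p2) {
  cont <- contingency_table(p1, p2)
  N <- sum(cont)
  pa <- rowSums(cont) / N
  pb <- colSums(cont) / N
  H1 <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  H2 <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (H1 == 0 && H2 == 0) return(1)
  if (H1 == 0 || H2 == 0) return(0)
  pij <- cont / N
  pe <- outer(pa, pb)
  I <- sum(ifelse(pij > 0, pij * log(pij / pe), 0))
  I / ((H1 + H2) / 2)
}

#' Adjusted Rand index between two partitions
#'
#' The chance-corrected Rand index over all N(N-1)/2 node-pair
#' co-membership decisions, computed from the contingency table. Equals 1
#' iff the partitions are identical up to relabeling, is approximately 0
#' for random agreement, and can be negative when agreement falls below its
#' chance expectation.
#'
#' When the chance-correction denominator is exactly zero (both partitions
#' trivial in the same way, so there is nothing to correct) the index is
#' defined as 1.
#'
#' @param p1,p2 `partition`s on the same node set.
#' @return Similarity \eqn{\le 1}, possibly negative.
#' @export
ari <- function(p1, p2) {
  cont <- contingency_table(p1, p2)
  N <- sum(cont)
  ch2 <- function(x) x * (x - 1) / 2
  sum_nij <- sum(ch2(cont))
  sum_a <- sum(ch2(rowSums(cont)))
  sum_b <- sum(ch2(colSums(cont)))
  expected <- sum_a * sum_b / ch2(N)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_nij - expected) / denom
}

#' Intrinsic distance between optimized objective values
#'
#' p-norm distance \eqn{\|v_1 - v_2\|_p} between the optimized objective
#' values (modularity or Potts Hamiltonian) of two detection runs -- the
#' intrinsic cluster evaluation metric, requiring no node-level comparison.
#' For the usual scalar objectives every p-norm reduces to the absolute
#' difference; vector objectives (e.g. across several resolutions) are
#' supported.
#'
#' @param v1,v2 numeric objective value(s) from the *same* algorithm family
#'   (both modularity or both Hamiltonian).
#' @param p norm order, `1 <= p < Inf`.
#' @return Non-negative distance.
#' @export
objective_distance <- function(v1, v2, p = 1) {
  if (p < 1 || !is.finite(p)) stop("p must satisfy 1 <= p < Inf")
  if (length(v1) != length(v2)) stop("objective vectors differ in length")
  if (anyNA(v1) || anyNA(v2)) stop("objective value missing")
  sum(abs(v1 - v2)^p)^(1 / p)
}

#' Pairwise distance matrix over a cohort of partitions
#'
#' Assembles the n x n subject dissimilarity matrix feeding the distance
#' kernel. For the extrinsic metrics the distance is `1 - similarity`
#' (purity, NMI, ARI); a negative ARI therefore yields a distance above 1,
#' which is allowed and propagates into the kernel unchanged. For the
#' intrinsic metric the distance is the p-norm difference of optimized
#' objective values, which requires all partitions to come from the same
#' algorithm family.
#'
#' @param partitions list of `partition`s (shared node set for extrinsic
#'   metrics; objective values present for the intrinsic metric).
#' @param metric `"purity"`, `"nmi"`, `"ari"`, or `"objective"`.
#' @param p norm order for the intrinsic metric.
#' @param subject_ids optional subject labels.
#' @return A [subject_dist()] matrix.
#' @export
partition_distances <- function(partitions,
                                metric = c("purity", "nmi", "ari", "objective"),
                                p = 1, subject_ids = NULL) {
  metric <- match.arg(metric)
  n <- length(partitions)
  if (n < 2) stop("need at least two partitions")
  if (metric == "objective") {
    algs <- unique(vapply(partitions, function(x) x$algorithm, character(1)))
    if (length(algs) > 1)
      stop("incompatible metric: objective values from different algorithms (",
           paste(algs, collapse = ", "), ")")
    v <- vapply(partitions, function(x) x$objective, numeric(1))
    if (anyNA(v)) stop("objective value missing for some partitions")
    d <- abs(outer(v, v, "-"))  # scalar objectives: every p-norm is |diff|
  } else {
    d <- pairwise_extrinsic_dists(partitions)[[metric]]
  }
  d[d < 0] <- 0  # guard float underflow at ~1e-16
  diag(d) <- 0
  subject_dist((d + t(d)) / 2, subject_ids = subject_ids, metric = metric, p = p)
}

# all three extrinsic distance matrices in one C++ pass over subject pairs
pairwise_extrinsic_dists <- function(partitions) {
  ref <- names(partitions[[1]]$membership)
  labs <- t(vapply(partitions, function(p) {
    check_same_nodes(partitions[[1]], p)
    m <- p$membership[ref]
    match(m, unique(m))
  }, integer(length(ref))))
  pairwise_extrinsic_cpp(labs)
}
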