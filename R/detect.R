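#' Weighted Newman-Girvan modularity of a partition
#'
#' Direct evaluation of
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_i k_j}{2m}\right]
#'   \delta(c_i, c_j),}
#' with weighted degrees \eqn{k_i} and total edge weight \eqn{m}.
#'
#' @param net a [weighted_network()].
#' @param membership community labels in the node order of `net` (or a
#'   `partition`).
#' @return The modularity Q.
#' @export
modularity_value <- function(net, membership) {
  if (inherits(membership, "partition"))
    membership <- membership$membership[net$node_ids]
  A <- net$weights
  two_m <- sum(A)
  if (two_m <= 0) stop("degenerate network: no positive edge weight")
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / two_m) * same) / two_m
}

#' Potts Hamiltonian of a spin configuration
#'
#' Direct evaluation of the Reichardt-Bornholdt energy
#' \deqn{H(\sigma) = -\sum_{i<j}\left[A_{ij} - \gamma p_{ij}\right]
#'   \delta(\sigma_i, \sigma_j)}
#' with the configuration-model null \eqn{p_{ij} = k_i k_j / 2m}. Lower is
#' better; community detection by spinglass seeks the ground state.
#'
#' @param net a [weighted_network()].
#' @param membership spin labels in node order (or a `partition`).
#' @param gamma resolution parameter (default 1).
#' @return The Hamiltonian H (signed; typically negative).
#' @export
hamiltonian_value <- function(net, membership, gamma = 1) {
  if (inherits(membership, "partition"))
    membership <- membership$membership[net$node_ids]
  A <- net$weights
  two_m <- sum(A)
  if (two_m <= 0) stop("degenerate network: no positive edge weight")
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  ut <- upper.tri(A)
  -sum(((A - gamma * outer(k, k) / two_m) * same)[ut])
}

#' Louvain community detection
#'
#' Agglomerative modularity maximization: each node starts as its own
#' community and nodes/communities are greedily merged while modularity
#' improves. Delegates to [igraph::cluster_louvain()]; the returned
#' objective is this package's own direct modularity evaluation of the final
#' partition, so it can be checked against an independent computation.
#'
#' Louvain is stochastic (node scan order); seed the R RNG for
#' reproducibility.
#'
#' @param net a [weighted_network()] with at least one positive edge weight.
#' @return A `partition` with `algorithm = "louvain"` and `objective` = Q.
#' @export
detect_louvain <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  if (sum(net$weights) <= 0)
    stop("degenerate network: all edge weights are zero")
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_louvain(g)
  mem <- igraph::membership(cl)
  mem <- as.integer(mem)
  names(mem) <- net$node_ids
  partition(mem, objective = modularity_value(net, mem),
            algorithm = "louvain", converged = TRUE)
}

#' Spinglass community detection by simulated annealing
#'
#' Finds a low-energy state of the Potts Hamiltonian (see
#' [hamiltonian_value()]) over spin states `1..max_communities` by simulated
#' annealing with geometric cooling. Empty spin states are allowed: the
#' ground state may occupy fewer than `max_communities` communities.
#'
#' The schedule starts at `t0`, multiplies the temperature by `cool` after
#' each level, runs `sweeps` full sweeps (of N single-node proposals each)
#' per level, and stops at `t_min` or as soon as a whole level accepts no
#' move (frozen). If the schedule bottoms out while moves are still being
#' accepted the best state seen is returned with `converged = FALSE`.
#'
#' @param net a [weighted_network()].
#' @param max_communities maximum number of spin states (>= 2).
#' @param gamma resolution parameter of the null-model term.
#' @param t0,t_min,cool,sweeps annealing schedule: initial temperature,
#'   stopping temperature, geometric cooling factor, and sweeps per
#'   temperature level (`NULL` = N sweeps, one per node).
#' @return A `partition` with `algorithm = "spinglass"`, `objective` = H of
#'   the returned state, and a `converged` flag.
#' @export
detect_spinglass <- function(net, max_communities = 4, gamma = 1,
                             t0 = 1, t_min = 1e-3, cool = 0.99,
                             sweeps = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (max_communities < 2) stop("max_communities must be at least 2")
  if (sum(net$weights) <= 0)
    stop("degenerate network: all edge weights are zero")
  n <- n_nodes(net)
  if (is.null(sweeps)) sweeps <- n
  res <- spinglass_anneal_cpp(net$weights, as.integer(max_communities),
                              gamma, t0, t_min, cool, as.integer(sweeps))
  mem <- res$membership
  names(mem) <- net$node_ids
  partition(mem, objective = res$energy, algorithm = "spinglass",
            converged = res$frozen)
}

#' Consensus number of communities across a cohort
#'
#' Runs spinglass on every network for every candidate `max_communities` and
#' returns the modal number of *non-empty* communities across all runs --
#' the cohort-level consensus community count.
#'
#' @param nets list of [weighted_network()]s.
#' @param candidate_range integer vector of candidate `max_communities`
#'   values (e.g. `3:10`).
#' @param ... further arguments passed to [detect_spinglass()].
#' @return The modal non-empty community count (ties broken toward the
#'   smaller count).
#' @export
consensus_community_count <- function(nets, candidate_range, ...) {
  if (length(candidate_range) == 0) stop("candidate_range must be non-empty")
  counts <- unlist(lapply(nets, function(net) {
    vapply(candidate_range, function(k) {
      n_communities(detect_spinglass(net, max_communities = k, ...))
    }, integer(1))
  }))
  tab <- table(counts)
  as.integer(names(tab)[which.max(tab)])
}

#' Detect communities in every network of a cohort
#'
#' @param cohort a `network_cohort` (or plain list of networks).
#' @param algorithm `"louvain"` or `"spinglass"`.
#' @param ... passed to the detector.
#' @return A list of `partition`s, one per network.
#' @export
detect_cohort <- function(cohort, algorithm = c("louvain", "spinglass"), ...) {
  algorithm <- match.arg(algorithm)
  nets <- if (inherits(cohort, "network_cohort")) cohort$networks else cohort
  det <- switch(algorithm, louvain = detect_louvain,
                spinglass = detect_spinglass)
  lapply(nets, det, ...)
}
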