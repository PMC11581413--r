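#' Simulation design for planted-community weighted networks
#'
#' Describes one generating process: network order, number of planted
#' communities, the Beta shape parameters for within- and between-community
#' edge weights, and the per-node community perturbation probability that
#' controls inter-subject variability.
#'
#' Edge weights live on \[0, 1\], the support of the Beta distribution, which
#' matches non-negative correlation-like connectivity strengths. Well or
#' poorly separated community structure is dialed in through the shape
#' parameters: e.g. within `Beta(8, 8)` (mean 0.5) against between
#' `Beta(1.5, 8)` (mean ~0.16) gives strongly separated communities.
#'
#' @param n_nodes number of nodes N.
#' @param n_communities number of planted communities (<= `n_nodes`).
#' @param within length-2 positive numeric `(alpha, beta)` for
#'   within-community edge weights.
#' @param between length-2 positive numeric `(alpha, beta)` for
#'   between-community edge weights.
#' @param perturb_prob per-node probability of reassigning the node's master
#'   community label, in \[0, 1\].
#'
#' @return An object of class `sim_design`.
#' @export
#' @examples
#' sim_design(50, 3, within = c(8, 8), between = c(1.5, 8), perturb_prob = 0.1)
sim_design <- function(n_nodes, n_communities,
                       within = c(8, 8), between = c(1.5, 8),
                       perturb_prob = 0.1) {
  n_nodes <- as.integer(n_nodes)
  n_communities <- as.integer(n_communities)
  if (n_nodes < 1) stop("n_nodes must be positive")
  if (n_communities < 1 || n_communities > n_nodes)
    stop("invalid design: need 1 <= n_communities <= n_nodes")
  if (length(within) != 2 || length(between) != 2 ||
      any(c(within, between) <= 0))
    stop("Beta shape parameters must be two positive numbers each")
  if (perturb_prob < 0 || perturb_prob > 1)
    stop("perturb_prob must lie in [0, 1]")
  structure(list(n_nodes = n_nodes, n_communities = n_communities,
                 within = as.numeric(within), between = as.numeric(between),
                 perturb_prob = perturb_prob),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "<sim_design> %d nodes, %d communities, within Beta(%g,%g), between Beta(%g,%g), perturb %.2f\n",
    x$n_nodes, x$n_communities, x$within[1], x$within[2],
    x$between[1], x$between[2], x$perturb_prob))
  invisible(x)
}

#' Draw a master community assignment
#'
#' Assigns every node of the design to one of its communities uniformly at
#' random, redrawing until every community is non-empty.
#'
#' @param design a [sim_design()].
#' @return A `partition` with `algorithm = "planted"`.
#' @export
make_master_assignment <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  k <- design$n_communities
  n <- design$n_nodes
  repeat {
    labels <- sample.int(k, n, replace = TRUE)
    if (length(unique(labels)) == k) break
  }
  names(labels) <- paste0("n", seq_len(n))
  partition(labels, algorithm = "planted")
}

#' Perturb a community assignment
#'
#' Each node is independently flagged with probability `perturb_prob`;
#' flagged nodes are reassigned to a community label drawn uniformly from the
#' *other* labels present in the master assignment (so a flagged node always
#' changes community when at least two communities exist). This is the
#' inter-subject variability mechanism: each subject's planted structure is
#' an independently perturbed copy of the cohort master.
#'
#' @param master a `partition` to perturb.
#' @param perturb_prob probability in \[0, 1\].
#' @return A perturbed `partition` (`algorithm = "planted"`).
#' @export
perturb_assignment <- function(master, perturb_prob) {
  stopifnot(inherits(master, "partition"))
  if (perturb_prob < 0 || perturb_prob > 1)
    stop("perturb_prob must lie in [0, 1]")
  labels <- master$membership
  pool <- unique(labels)
  if (perturb_prob == 0 || length(pool) < 2)
    return(partition(labels, algorithm = "planted"))
  flagged <- which(runif(length(labels)) < perturb_prob)
  for (i in flagged) {
    others <- pool[pool != labels[i]]
    labels[i] <- if (length(others) == 1) others else sample(others, 1)
  }
  partition(labels, algorithm = "planted")
}

#' Simulate one weighted network from a planted assignment
#'
#' Every unordered dyad receives an independent Beta-distributed weight:
#' from the within-community distribution when the two nodes share a
#' community, from the between-community distribution otherwise. The result
#' is symmetric with a zero diagonal.
#'
#' @param assignment a `partition` giving each node's community.
#' @param within,between length-2 `(alpha, beta)` Beta shape parameters.
#' @return A [weighted_network()].
#' @export
simulate_network <- function(assignment, within, between) {
  stopifnot(inherits(assignment, "partition"))
  labels <- assignment$membership
  n <- length(labels)
  ut <- upper.tri(matrix(0, n, n))
  same <- outer(labels, labels, "==")[ut]
  w <- numeric(sum(ut))
  nw <- sum(same)
  if (nw > 0) w[same] <- rbeta(nw, within[1], within[2])
  if (nw < length(w)) w[!same] <- rbeta(length(w) - nw, between[1], between[2])
  m <- matrix(0, n, n)
  m[ut] <- w
  m <- m + t(m)
  weighted_network(m, node_ids = names(labels), validate = FALSE)
}

#' Simulate a case/control cohort of weighted networks
#'
#' Draws one master community assignment (shared between groups by default),
#' then builds each subject's network by independently perturbing the master
#' and sampling dyadic weights from the group's Beta distributions. Under the
#' null scenario the two designs are identical, so the group label is
#' independent of the network distribution.
#'
#' @param n_case,n_control group sizes.
#' @param case_design,control_design [sim_design()]s; must agree on
#'   `n_nodes` and `n_communities`.
#' @param shared_master if `TRUE` (default) one master assignment is drawn
#'   for the whole cohort; otherwise each group gets its own master.
#' @param seed optional integer seed; when supplied the cohort is a
#'   deterministic function of the seed.
#'
#' @return A list of class `network_cohort` with elements `networks` (list of
#'   [weighted_network()]), `group` (integer 0/1, 1 = case), `assignments`
#'   (the perturbed planted partitions), `subject_ids`, and `master`.
#' @export
#' @examples
#' d <- sim_design(20, 3, perturb_prob = 0.1)
#' coh <- simulate_cohort(4, 6, d, d, seed = 1)
#' table(coh$group)
simulate_cohort <- function(n_case, n_control,
                            case_design, control_design = case_design,
                            shared_master = TRUE, seed = NULL) {
  stopifnot(inherits(case_design, "sim_design"),
            inherits(control_design, "sim_design"))
  if (case_design$n_nodes != control_design$n_nodes ||
      case_design$n_communities != control_design$n_communities)
    stop("invalid design: case and control designs must agree on n_nodes and n_communities")
  if (n_case < 0 || n_control < 0 || n_case + n_control < 1)
    stop("need at least one subject")
  if (!is.null(seed)) set.seed(seed)

  master_case <- make_master_assignment(case_design)
  master_control <- if (shared_master) master_case else
    make_master_assignment(control_design)

  n <- n_case + n_control
  group <- rep(c(1L, 0L), c(n_case, n_control))
  networks <- vector("list", n)
  assignments <- vector("list", n)
  for (i in seq_len(n)) {
    des <- if (group[i] == 1L) case_design else control_design
    mas <- if (group[i] == 1L) master_case else master_control
    assignments[[i]] <- perturb_assignment(mas, des$perturb_prob)
    networks[[i]] <- simulate_network(assignments[[i]], des$within, des$between)
  }
  ids <- sprintf("s%03d", seq_len(n))
  structure(list(networks = networks, group = group,
                 assignments = assignments, subject_ids = ids,
                 master = master_case,
                 master_control = if (shared_master) NULL else master_control),
            class = "network_cohort")
}

#' @export
print.network_cohort <- function(x, ...) {
  cat(sprintf("<network_cohort> %d subjects (%d cases / %d controls), %d nodes\n",
              length(x$networks), sum(x$group == 1L), sum(x$group == 0L),
              n_nodes(x$networks[[1]])))
  invisible(x)
}
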