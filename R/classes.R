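#' Weighted undirected network
#'
#' The unit of observation: a symmetric, non-negative adjacency matrix over a
#' labeled node set, with zero diagonal and edge weights in \[0, 1\]
#' (correlation-like connection strengths, as produced by functional
#' connectivity pipelines after zeroing negative correlations).
#'
#' @param weights numeric N x N symmetric matrix, zero diagonal, entries in
#'   \[0, 1\].
#' @param node_ids character vector of node labels (defaults to the dimnames
#'   of `weights`, or `"n1"..."nN"`).
#' @param validate logical; skip validation for trusted internal callers.
#'
#' @return An object of class `weighted_network`: a list with elements
#'   `node_ids` and `weights` (dimnames set to `node_ids`).
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.5
#' weighted_network(w)
weighted_network <- function(weights, node_ids = NULL, validate = TRUE) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (is.null(node_ids)) {
    node_ids <- rownames(weights)
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (validate) {
    if (ncol(weights) != n) stop("adjacency matrix must be square")
    if (length(node_ids) != n) stop("node_ids length must match matrix order")
    if (anyDuplicated(node_ids)) stop("node_ids must be unique")
    if (anyNA(weights)) stop("adjacency contains missing values")
    if (max(abs(weights - t(weights))) > 1e-10)
      stop("adjacency matrix is not symmetric (tolerance 1e-10)")
    if (any(diag(weights) != 0)) stop("self-loops are not allowed (diagonal must be 0)")
    if (min(weights) < 0 || max(weights) > 1)
      stop("edge weights must lie in [0, 1]")
  }
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, weights = weights),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<weighted_network> %d nodes, mean weight %.3f (range %.3f-%.3f)\n",
              length(x$node_ids), mean(w), min(w), max(w)))
  invisible(x)
}

n_nodes <- function(net) length(net$node_ids)

#' Node-to-community partition
#'
#' A community assignment of the nodes of one network, together with the
#' optimized objective value when the partition came out of a detection
#' algorithm (modularity for Louvain, Potts Hamiltonian for spinglass).
#' Community labels are arbitrary: partitions are compared only up to
#' relabeling.
#'
#' @param membership integer (or coercible) vector of community labels, named
#'   by node id; unnamed vectors get `"n1"..."nN"`.
#' @param objective optimized objective value; `NA` for planted / externally
#'   supplied partitions.
#' @param algorithm one of `"louvain"`, `"spinglass"`, `"planted"`.
#' @param converged logical; `FALSE` marks a spinglass run that was still
#'   accepting moves when the cooling schedule bottomed out.
#'
#' @return An object of class `partition`.
#' @export
partition <- function(membership,
                      objective = NA_real_,
                      algorithm = c("planted", "louvain", "spinglass"),
                      converged = NA) {
  algorithm <- match.arg(algorithm)
  m <- as.integer(membership)
  if (anyNA(m)) stop("membership contains missing labels")
  nm <- names(membership)
  if (is.null(nm)) nm <- paste0("n", seq_along(m))
  if (anyDuplicated(nm)) stop("duplicated node ids in membership")
  names(m) <- nm
  structure(list(membership = m,
                 objective = as.numeric(objective),
                 algorithm = algorithm,
                 converged = converged),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  sizes <- table(x$membership)
  cat(sprintf("<partition:%s> %d nodes in %d communities (sizes %s)%s\n",
              x$algorithm, length(x$membership), length(sizes),
              paste(as.integer(sizes), collapse = "/"),
              if (is.na(x$objective)) "" else sprintf(", objective %.4f", x$objective)))
  invisible(x)
}

n_communities <- function(p) length(unique(p$membership))

# shared-node-set guard for extrinsic metrics: both partitions must cover the
# identical node set (networks must be of the same size)
check_same_nodes <- function(p1, p2) {
  n1 <- names(p1$membership); n2 <- names(p2$membership)
  if (length(n1) != length(n2) || !setequal(n1, n2))
    stop("partitions are not defined on the same node set")
  invisible(TRUE)
}

# align p2's labels to p1's node order; returns a 2-column integer matrix of
# dense labels 1..k1 / 1..k2
aligned_labels <- function(p1, p2) {
  check_same_nodes(p1, p2)
  a <- p1$membership
  b <- p2$membership[names(a)]
  cbind(match(a, unique(a)), match(b, unique(b)))
}

#' Pairwise subject distance matrix
#'
#' Symmetric non-negative dissimilarities between subjects' community
#' partitions under a chosen cluster evaluation metric. Stored as a plain
#' matrix with subject ids as dimnames and the metric recorded as an
#' attribute.
#'
#' @param d numeric n x n symmetric matrix, zero diagonal, non-negative.
#' @param subject_ids character labels for the n subjects.
#' @param metric one of `"purity"`, `"nmi"`, `"ari"`, `"objective"`.
#' @param p p-norm order used for the intrinsic (objective) metric.
#'
#' @return An object of class `subject_dist` (a matrix).
#' @export
subject_dist <- function(d, subject_ids = NULL,
                         metric = c("purity", "nmi", "ari", "objective"),
                         p = 1) {
  metric <- match.arg(metric)
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n) stop("distance matrix must be square")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(d)
    if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  }
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (min(d) < 0) stop("distances must be non-negative")
  dimnames(d) <- list(subject_ids, subject_ids)
  structure(d, metric = metric, p = p, class = c("subject_dist", "matrix", "array"))
}

#' @export
print.subject_dist <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("<subject_dist:%s> %d subjects, distances %.4f-%.4f (mean %.4f)\n",
              attr(x, "metric"), nrow(x), min(off), max(off), mean(off)))
  invisible(x)
}
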