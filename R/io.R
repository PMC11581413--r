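#' Write / read a weighted network
#'
#' Two plain-text dialects: `"dense_csv"` stores the full symmetric matrix
#' with node ids as header row and first column (human-inspectable,
#' round-trips bit-exactly via decimal text); `"edge_list"` stores the
#' strictly-upper-triangle dyads as `node_i, node_j, weight` rows, omitting
#' zero-weight dyads.
#'
#' @param net a [weighted_network()].
#' @param path output file.
#' @param format `"dense_csv"` or `"edge_list"`.
#' @export
write_adjacency <- function(net, path, format = c("dense_csv", "edge_list")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "weighted_network"))
  if (format == "dense_csv") {
    df <- data.frame(node_id = net$node_ids,
                     format(net$weights, digits = 17, trim = TRUE),
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    w <- net$weights
    ut <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    df <- data.frame(node_i = net$node_ids[ut[, 1]],
                     node_j = net$node_ids[ut[, 2]],
                     weight = format(w[ut], digits = 17, trim = TRUE))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_adjacency
#' @param clip_negative if `TRUE`, negative weights are zeroed (with a
#'   message) instead of rejected -- the convention used when connectivity
#'   comes from correlations whose negative values must be discarded.
#' @return `read_adjacency()`: a [weighted_network()]. Missing dyads in an
#'   edge list get weight 0; dense input must be symmetric to 1e-10.
#' @export
read_adjacency <- function(path, format = c("dense_csv", "edge_list"),
                           clip_negative = FALSE) {
  format <- match.arg(format)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "dense_csv") {
    ids <- as.character(df[[1]])
    w <- as.matrix(df[, -1, drop = FALSE])
    mode(w) <- "numeric"
    if (!identical(colnames(w), ids))
      stop("dense adjacency header and node-id column disagree")
  } else {
    ids <- sort(unique(c(df$node_i, df$node_j)))
    w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    i <- match(df$node_i, ids); j <- match(df$node_j, ids)
    w[cbind(i, j)] <- df$weight
    w[cbind(j, i)] <- df$weight
  }
  if (any(w < 0)) {
    if (!clip_negative)
      stop("negative edge weights present; pass clip_negative = TRUE to zero them")
    message(sum(w < 0), " negative weight(s) zeroed")
    w[w < 0] <- 0
  }
  weighted_network(w, node_ids = ids)
}

#' Write / read a partition
#'
#' Two-column delimited text (`node_id, community`) plus a sidecar
#' `<path>.meta` record (DCF key:value lines) carrying the algorithm tag,
#' the optimized objective value and the convergence flag.
#'
#' @param p a `partition`.
#' @param path output file.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "partition"))
  df <- data.frame(node_id = names(p$membership), community = p$membership)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- data.frame(algorithm = p$algorithm,
                     objective = format(p$objective, digits = 17),
                     converged = as.character(p$converged))
  write.dcf(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_partition
#' @return `read_partition()`: a `partition` (objective/algorithm restored
#'   from the sidecar when present).
#' @export
read_partition <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mem <- df$community
  names(mem) <- df$node_id
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- as.data.frame(read.dcf(meta_path), stringsAsFactors = FALSE)
    obj <- if (identical(meta$objective, "NA")) NA_real_ else
      as.numeric(meta$objective)
    partition(mem, objective = obj,
              algorithm = meta$algorithm,
              converged = as.logical(meta$converged))
  } else {
    partition(mem)
  }
}

#' Write / read a subject distance matrix
#'
#' Dense CSV with subject ids as header row and first column; the metric
#' tag travels in a sidecar `<path>.meta` record.
#'
#' @param D a [subject_dist()].
#' @param path output file.
#' @export
write_subject_dist <- function(D, path) {
  stopifnot(inherits(D, "subject_dist"))
  df <- data.frame(subject_id = rownames(D),
                   format(unclass(D), digits = 17, trim = TRUE),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  write.dcf(data.frame(metric = attr(D, "metric"), p = attr(D, "p")),
            paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_subject_dist
#' @export
read_subject_dist <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  d <- as.matrix(df[, -1, drop = FALSE])
  mode(d) <- "numeric"
  meta_path <- paste0(path, ".meta")
  metric <- "nmi"; p <- 1
  if (file.exists(meta_path)) {
    meta <- as.data.frame(read.dcf(meta_path), stringsAsFactors = FALSE)
    metric <- meta$metric; p <- as.numeric(meta$p)
  }
  subject_dist(d, subject_ids = ids, metric = metric, p = p)
}

#' Read a phenotype table
#'
#' CSV with a `subject_id` column, one outcome column and optional
#' covariate columns. Rows with a missing outcome are dropped with a
#' message (as happens when, say, a cognitive score was not collected for
#' part of a cohort); duplicated subject ids are an error. Downstream
#' alignment against a distance matrix is always by id, never by row
#' position.
#'
#' @param path CSV file.
#' @param outcome name of the outcome column.
#' @param id_col name of the subject id column.
#' @return A data.frame keyed by `subject_id` with complete outcomes.
#' @export
read_phenotypes <- function(path, outcome, id_col = "subject_id") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!id_col %in% names(df)) stop("missing id column '", id_col, "'")
  if (!outcome %in% names(df)) stop("missing outcome column '", outcome, "'")
  if (anyDuplicated(df[[id_col]]))
    stop("duplicated subject ids in phenotype table")
  miss <- is.na(df[[outcome]])
  if (any(miss)) {
    message("dropping ", sum(miss), " subject(s) with missing outcome")
    df <- df[!miss, , drop = FALSE]
  }
  rownames(df) <- df[[id_col]]
  df
}

#' Write a simulated cohort to disk
#'
#' One dense-CSV adjacency and one planted-partition file per subject, plus
#' a `manifest.csv` (subject_id, group, adjacency, partition) tying them
#' together.
#'
#' @param cohort a `network_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "network_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  adj <- file.path(dir, paste0(cohort$subject_ids, "_adj.csv"))
  part <- file.path(dir, paste0(cohort$subject_ids, "_planted.csv"))
  for (i in seq_along(cohort$networks)) {
    write_adjacency(cohort$networks[[i]], adj[i])
    write_partition(cohort$assignments[[i]], part[i])
  }
  manifest <- data.frame(subject_id = cohort$subject_ids,
                         group = cohort$group,
                         adjacency = basename(adj),
                         partition = basename(part))
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path path to a `manifest.csv` written by
#'   [write_cohort()].
#' @return A `network_cohort` (planted assignments included).
#' @export
read_cohort <- function(manifest_path) {
  dir <- dirname(manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (anyDuplicated(man$subject_id)) stop("duplicated subject ids in manifest")
  paths <- file.path(dir, c(man$adjacency, man$partition))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("manifest refers to missing file(s): ",
         paste(basename(missing), collapse = ", "))
  networks <- lapply(file.path(dir, man$adjacency), read_adjacency)
  assignments <- lapply(file.path(dir, man$partition), read_partition)
  structure(list(networks = networks, group = as.integer(man$group),
                 assignments = assignments, subject_ids = man$subject_id,
                 master = NULL, master_control = NULL),
            class = "network_cohort")
}
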