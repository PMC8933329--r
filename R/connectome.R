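#' Count region-to-region connections from streamline endpoints
#'
#' Each fiber increments the cell for (region of first endpoint, region of
#' last endpoint) once, symmetrically.  Fibers with an endpoint in background
#' (label 0) or with both endpoints in the same region are dropped; their
#' counts are returned alongside the matrix.  Endpoint-only assignment is
#' deliberate — pass-through counting would inflate hub connectivity.
#'
#' @param fibers list of `n x 3` world-mm matrices (already VR-selected and
#'   length-filtered).
#' @param parcellation a [parcellation] object.
#' @return List with `counts` (symmetric integer matrix, region ids as
#'   dimnames), `used`, `dropped_unassigned`, `dropped_same_region`.
#' @export
count_connections <- function(fibers, parcellation) {
  ids <- parcellation$regions$id
  n <- length(ids)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  used <- 0L; unassigned <- 0L; same <- 0L
  if (length(fibers) > 0L) {
    ends <- do.call(rbind, lapply(fibers, function(s) {
      s[c(1L, nrow(s)), , drop = FALSE]
    }))
    lab <- labels_at(ends, parcellation$volume)
    a <- lab[seq(1L, length(lab), by = 2L)]
    b <- lab[seq(2L, length(lab), by = 2L)]
    ia <- match(a, ids)
    ib <- match(b, ids)
    drop_bg <- a == 0L | b == 0L | is.na(ia) | is.na(ib)
    drop_same <- !drop_bg & a == b
    keep <- !drop_bg & !drop_same
    unassigned <- sum(drop_bg)
    same <- sum(drop_same)
    used <- sum(keep)
    if (used > 0L) {
      for (k in which(keep)) {
        counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1L
        counts[ib[k], ia[k]] <- counts[ib[k], ia[k]] + 1L
      }
    }
  }
  list(counts = counts, used = used,
       dropped_unassigned = unassigned, dropped_same_region = same)
}

#' Binarize a fiber-count matrix
#'
#' A region pair counts as connected only when it carries strictly more than
#' `min_count` fibers ("more than three" by default); the diagonal is forced
#' to zero.
#'
#' @param counts symmetric count matrix.
#' @param min_count connections with `counts > min_count` become edges.
#' @return 0/1 integer adjacency matrix with the same dimnames.
#' @export
binarize <- function(counts, min_count = 3L) {
  adj <- (counts > min_count) + 0L
  diag(adj) <- 0L
  dimnames(adj) <- dimnames(counts)
  adj
}

#' Induced subgraph of an adjacency (or count) matrix
#'
#' @param adjacency square matrix with region-id dimnames.
#' @param node_subset region ids to keep (order preserved as given).
#' @return The induced submatrix; unknown ids are an error.
#' @export
submatrix <- function(adjacency, node_subset) {
  ids <- rownames(adjacency)
  idx <- match(as.character(node_subset), ids)
  if (anyNA(idx)) {
    stop("unknown node id(s): ",
         paste(node_subset[is.na(idx)], collapse = ", "))
  }
  adjacency[idx, idx, drop = FALSE]
}

#' Average degree of a binarized network
#'
#' `2E / N`: twice the edge count over the node count.
#'
#' @param adjacency symmetric 0/1 matrix, zero diagonal.
#' @return Non-negative real; 0 for an empty node set.
#' @export
average_degree <- function(adjacency) {
  n <- nrow(adjacency)
  if (is.null(n) || n == 0L) return(0)
  sum(adjacency) / n
}

#' All-pairs shortest path lengths (unweighted)
#'
#' Vectorized Floyd-Warshall; `Inf` for disconnected pairs.
#'
#' @param adjacency symmetric 0/1 matrix.
#' @return Distance matrix.
#' @keywords internal
shortest_path_lengths <- function(adjacency) {
  n <- nrow(adjacency)
  d <- ifelse(adjacency > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    lower <- dk < d
    if (any(lower)) d[lower] <- dk[lower]
  }
  d
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs
#' (Latora-Marchiori); disconnected pairs contribute 0, and a network with
#' fewer than two nodes has efficiency 0.
#'
#' @param adjacency symmetric 0/1 matrix, zero diagonal.
#' @return Value in `[0, 1]`.
#' @export
global_efficiency <- function(adjacency) {
  n <- nrow(adjacency)
  if (is.null(n) || n < 2L) return(0)
  d <- shortest_path_lengths(adjacency)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's neighbors; nodes with fewer than two neighbors contribute 0.
#'
#' @param adjacency symmetric 0/1 matrix, zero diagonal.
#' @return Value in `[0, 1]`.
#' @export
local_efficiency <- function(adjacency) {
  n <- nrow(adjacency)
  if (is.null(n) || n == 0L) return(0)
  acc <- 0
  for (i in seq_len(n)) {
    nb <- which(adjacency[i, ] > 0)
    if (length(nb) >= 2L) {
      acc <- acc + global_efficiency(adjacency[nb, nb, drop = FALSE])
    }
  }
  acc / n
}

#' Graph metrics of one binarized matrix
#'
#' @param adjacency symmetric 0/1 matrix.
#' @return Named list `ad`, `eg`, `el`; all 0 for matrices with fewer than
#'   two nodes.
#' @export
graph_metrics <- function(adjacency) {
  n <- nrow(adjacency)
  if (is.null(n) || n < 2L) return(list(ad = 0, eg = 0, el = 0))
  list(
    ad = average_degree(adjacency),
    eg = global_efficiency(adjacency),
    el = local_efficiency(adjacency)
  )
}

#' Metric differences between the two VR thresholds
#'
#' `value(lower threshold) - value(higher threshold)`, e.g. 25% VR minus
#' 50% VR.  Under nested edge sets `ad_diff` and `eg_diff` are non-negative;
#' local efficiency is not monotone and its difference may take either sign.
#'
#' @param metrics_low,metrics_high `list(ad, eg, el)` at the lower and higher
#'   VR threshold.
#' @return Named list `ad_diff`, `eg_diff`, `el_diff`.
#' @export
diff_metrics <- function(metrics_low, metrics_high) {
  list(
    ad_diff = metrics_low$ad - metrics_high$ad,
    eg_diff = metrics_low$eg - metrics_high$eg,
    el_diff = metrics_low$el - metrics_high$el
  )
}

#' Edge prevalence across a group of subjects
#'
#' Counts, per edge, how many subjects possess it; edges seen in fewer than
#' `min_subjects` subjects are masked (zeroed) in the exported matrix, the
#' rule used when rendering group networks.
#'
#' @param adjacencies list of subject adjacency matrices (same node set).
#' @param min_subjects minimum subject count for an edge to survive masking.
#' @return List with `prevalence` (integer matrix) and `masked`.
#' @export
group_edge_prevalence <- function(adjacencies, min_subjects = 1L) {
  stopifnot(length(adjacencies) >= 1L)
  prev <- Reduce(`+`, adjacencies)
  masked <- prev * (prev >= min_subjects)
  list(prevalence = prev, masked = masked)
}
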