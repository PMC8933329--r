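#' Assign world-mm points to parcellation regions
#'
#' A point takes the label of its containing voxel; if that voxel is
#' background, the nearest labeled voxel center within `search_radius_mm` is
#' used (distance ties broken by the smallest region id), since stimulation
#' sites sit on the cortical surface and may fall just outside the labeled
#' volume after registration.  Points with no labeled voxel in range are
#' unassigned (0).
#'
#' @param points `n x 3` world-mm matrix.
#' @param parcellation a `parcellation`.
#' @param search_radius_mm fallback search radius (mm), default 5.
#' @return Integer vector of region ids, 0 = unassigned.
#' @export
assign_points <- function(points, parcellation, search_radius_mm = 5) {
  points <- as_point_matrix(points)
  vol <- parcellation$volume
  lab <- labels_at(points, vol)
  todo <- which(lab == 0L)
  if (length(todo) == 0L || search_radius_mm <= 0) return(lab)
  lin <- which(vol$data > 0L)
  idx <- arrayInd(lin, vol$shape) - 1L
  centers <- voxel_to_world(idx, vol)
  labels <- vol$data[lin]
  r2 <- search_radius_mm^2
  for (i in todo) {
    p <- points[i, ]
    near <- which(abs(centers[, 1L] - p[1L]) <= search_radius_mm &
                  abs(centers[, 2L] - p[2L]) <= search_radius_mm &
                  abs(centers[, 3L] - p[3L]) <= search_radius_mm)
    if (length(near) == 0L) next
    d2 <- rowSums(sweep(centers[near, , drop = FALSE], 2L, p)^2)
    ok <- d2 <= r2 + 1e-9
    if (!any(ok)) next
    d2 <- d2[ok]
    cand <- labels[near[ok]]
    best <- d2 <= min(d2) + 1e-9
    lab[i] <- min(cand[best])
  }
  lab
}

#' @rdname assign_points
#' @param point length-3 world-mm point.
#' @export
assign_point <- function(point, parcellation, search_radius_mm = 5) {
  assign_points(matrix(point, ncol = 3L), parcellation, search_radius_mm)[1L]
}

#' Build a subject's stimulation map
#'
#' A region is positively mapped iff at least one POS point assigns to it,
#' negatively mapped iff at least one NEG point does; by default a region
#' may be both (`pos_precedence = TRUE` removes positive regions from the
#' negative set).  Unassigned points are dropped and counted.
#'
#' @param points data frame with `x`, `y`, `z`, `polarity` (one subject).
#' @param parcellation a `parcellation`.
#' @param search_radius_mm see [assign_points()].
#' @param pos_precedence drop positively mapped regions from the negative
#'   set.
#' @return List of class `stimulation_map`: `pos_regions`, `neg_regions`,
#'   `n_pos`, `n_neg`, `n_dropped`.
#' @export
build_stimulation_map <- function(points, parcellation, search_radius_mm = 5,
                                  pos_precedence = FALSE) {
  if (nrow(points) == 0L) {
    return(structure(list(pos_regions = integer(0), neg_regions = integer(0),
                          n_pos = 0L, n_neg = 0L, n_dropped = 0L),
                     class = "stimulation_map"))
  }
  stopifnot(all(points$polarity %in% c("POS", "NEG")))
  ids <- assign_points(as.matrix(points[, c("x", "y", "z")]), parcellation,
                       search_radius_mm)
  dropped <- sum(ids == 0L)
  if (dropped > 0L) {
    message(dropped, " stimulation point(s) unassigned within ",
            search_radius_mm, " mm; dropped")
  }
  pos <- sort(unique(ids[ids > 0L & points$polarity == "POS"]))
  neg <- sort(unique(ids[ids > 0L & points$polarity == "NEG"]))
  if (pos_precedence) neg <- setdiff(neg, pos)
  structure(list(pos_regions = pos, neg_regions = neg,
                 n_pos = length(pos), n_neg = length(neg),
                 n_dropped = dropped),
            class = "stimulation_map")
}

#' Intragroup mapping proportions per region
#'
#' For each region, group and polarity: the number and fraction of the
#' group's subjects in whose mapped set the region appears.
#'
#' @param cohort data frame with `group` and list-columns `pos_regions`,
#'   `neg_regions` (one row per subject).
#' @param parcellation a `parcellation`.
#' @param highlight_min regions mapped in at least this many subjects are
#'   flagged (`NULL` to skip flagging).
#' @return Data frame (`region`, `name`, `hemisphere`, `group`, `polarity`,
#'   `count`, `n_group`, `proportion`, and `highlighted` if requested).
#' @export
intragroup_proportions <- function(cohort, parcellation,
                                   highlight_min = NULL) {
  regions <- parcellation$regions
  groups <- unique(cohort$group)
  out <- list()
  for (g in groups) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    ng <- nrow(sub)
    for (pol in c("POS", "NEG")) {
      col <- if (pol == "POS") "pos_regions" else "neg_regions"
      tallies <- table(factor(unlist(sub[[col]]), levels = regions$id))
      counts <- as.integer(tallies)
      out[[length(out) + 1L]] <- data.frame(
        region = regions$id, name = regions$name,
        hemisphere = regions$hemisphere,
        group = g, polarity = pol, count = counts, n_group = ng,
        proportion = counts / ng, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(highlight_min)) res$highlighted <- res$count >= highlight_min
  rownames(res) <- NULL
  res
}
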