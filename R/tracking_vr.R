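#' Fiber record
#'
#' One streamline with its per-point FA samples, arc length, and the derived
#' thresholding quantities: `fa_max`, the largest FA threshold (on the
#' `grid_step` grid) at which a contiguous suprathreshold run of the fiber
#' still spans at least the fiber length threshold, and `vr`, that value as a
#' percentage of the subject-level maximum.
#'
#' @param points `n x 3` world-mm matrix.
#' @param fa per-point FA values (sampled via [sample_fa_along()] or supplied
#'   by a generator).
#' @return Object of class `fiber_record` with `points`, `fa`, `length_mm`,
#'   `fa_max` (NA until computed), `vr` (NA until computed).
#' @export
fiber_record <- function(points, fa) {
  points <- as_point_matrix(points)
  stopifnot(length(fa) == nrow(points))
  structure(
    list(points = points, fa = as.numeric(fa),
         length_mm = arc_length(points), fa_max = NA_real_, vr = NA_real_),
    class = "fiber_record"
  )
}

arc_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

segment_cumlen <- function(points) {
  if (nrow(points) < 2L) return(0)
  d <- diff(points)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

#' Per-fiber fa_max by threshold sweep
#'
#' Reformulation of the incremental-threshold tracking procedure as a single
#' pass over the fiber: the largest grid threshold `t` such that some
#' contiguous run of points with FA >= `t` has arc length >= `flt_mm`.
#' Equivalently, the grid floor of the maximum over windows of length
#' >= `flt_mm` of the window's minimum FA (extending a window can only lower
#' its minimum, so minimal windows suffice).  Returns `NA` when the whole
#' fiber is shorter than `flt_mm`.
#'
#' @param fiber a [fiber_record()] (or any list with `points` and `fa`).
#' @param flt_mm fiber length threshold in mm (default 30).
#' @param grid_step FA threshold grid (default 0.01).
#' @return `fa_max` on the grid, or `NA_real_`.
#' @export
famax_by_sweep <- function(fiber, flt_mm = 30, grid_step = 0.01) {
  fa <- fiber$fa
  cl <- segment_cumlen(fiber$points)
  famax_from_profile(fa, cl, flt_mm, grid_step)
}

famax_from_profile <- function(fa, cumlen, flt_mm, grid_step) {
  n <- length(fa)
  if (n < 2L || cumlen[n] < flt_mm - 1e-9) return(NA_real_)
  # minimal end index j for each start i with span >= flt_mm
  ends <- findInterval(cumlen + flt_mm - 1e-9, cumlen, left.open = TRUE) + 1L
  valid <- which(ends <= n)
  if (length(valid) == 0L) return(NA_real_)
  best <- max(vapply(valid, function(i) min(fa[i:ends[i]]), 0))
  floor((best + 1e-9) / grid_step) * grid_step
}

#' Subject tractogram with fa_max and FAT_max
#'
#' Computes `fa_max` for every fiber, drops fibers that cannot span the
#' fiber length threshold at any FA threshold (shorter than `flt_mm`), and
#' records the subject-level `fat_max`, the maximum of the per-fiber values.
#'
#' @param subject_id subject identifier.
#' @param fibers list of [fiber_record()]s.
#' @param flt_mm fiber length threshold (mm).
#' @param grid_step FA threshold grid.
#' @return Object of class `subject_tractogram` with `subject_id`, `fibers`
#'   (all with `fa_max` set), `fat_max`, `n_dropped_short`.
#' @export
subject_tractogram <- function(subject_id, fibers, flt_mm = 30,
                               grid_step = 0.01) {
  fam <- vapply(fibers, famax_by_sweep, 0, flt_mm = flt_mm,
                grid_step = grid_step)
  keep <- !is.na(fam)
  fibers <- fibers[keep]
  fam <- fam[keep]
  for (i in seq_along(fibers)) fibers[[i]]$fa_max <- fam[i]
  fat_max <- if (length(fam) > 0L) max(fam) else NA_real_
  structure(
    list(subject_id = subject_id, fibers = fibers, fat_max = fat_max,
         grid_step = grid_step, n_dropped_short = sum(!keep)),
    class = "subject_tractogram"
  )
}

#' @export
print.subject_tractogram <- function(x, ...) {
  cat(sprintf("<subject_tractogram> %s: %d fibers, FAT_max = %s\n",
              x$subject_id, length(x$fibers), format(x$fat_max)))
  invisible(x)
}

#' Visualized ratio (VR) for every fiber
#'
#' `VR = fa_max / FAT_max x 100`.  Thresholds live on an exact 0.01 grid, so
#' the ratio is computed on integer hundredths; the fiber attaining
#' `FAT_max` gets VR exactly 100.
#'
#' @param tractogram a [subject_tractogram()] with `fa_max` computed.
#' @return The tractogram with `vr` filled in on every fiber.
#' @export
compute_vr <- function(tractogram) {
  stopifnot(inherits(tractogram, "subject_tractogram"))
  if (length(tractogram$fibers) == 0L) return(tractogram)
  gs <- tractogram$grid_step
  ih_max <- as.integer(round(tractogram$fat_max / gs))
  if (is.na(ih_max) || ih_max == 0L) {
    stop("degenerate subject ", tractogram$subject_id,
         ": FAT_max is 0, VR undefined")
  }
  for (i in seq_along(tractogram$fibers)) {
    ih <- as.integer(round(tractogram$fibers[[i]]$fa_max / gs))
    tractogram$fibers[[i]]$vr <- 100 * ih / ih_max
  }
  tractogram
}

#' Select fibers at a VR threshold
#'
#' Inclusive rule: fibers with `vr >= vr_threshold_percent` are kept (so the
#' fiber defining `FAT_max` survives every threshold up to 100); order is
#' preserved.
#'
#' @param tractogram a [subject_tractogram()] after [compute_vr()].
#' @param vr_threshold_percent threshold in percent.
#' @return List of the selected [fiber_record()]s.
#' @export
select_fibers <- function(tractogram, vr_threshold_percent) {
  vr <- vapply(tractogram$fibers, function(f) f$vr, 0)
  tractogram$fibers[vr >= vr_threshold_percent - 1e-9]
}

#' Per-fiber summary table
#'
#' @param tractogram a [subject_tractogram()].
#' @return Data frame (fiber, length_mm, fa_max, vr).
#' @export
fiber_table <- function(tractogram) {
  data.frame(
    fiber = seq_along(tractogram$fibers),
    length_mm = vapply(tractogram$fibers, function(f) f$length_mm, 0),
    fa_max = vapply(tractogram$fibers, function(f) f$fa_max, 0),
    vr = vapply(tractogram$fibers, function(f) f$vr, 0)
  )
}
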