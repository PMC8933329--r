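#' Deterministic fixed-step streamline tracking at one FA threshold
#'
#' Principal-direction following on a voxel direction field: from every seed
#' the tracker steps `step_mm` at a time along the (sign-aligned,
#' trilinearly interpolated) direction field, in both directions, and
#' terminates when the interpolated FA drops below `fat`, the turning angle
#' exceeds `max_angle_deg`, the direction magnitude vanishes (outside any
#' bundle), or the volume edge is reached.  Only streamlines at least
#' `flt_mm` long are returned.  Fully deterministic: no randomness anywhere.
#'
#' @param direction_field 4-D array (`x, y, z, 3`) of unit tangent vectors
#'   (zero outside bundles).
#' @param fa_volume a [volume_grid()] of kind `"fa"`, co-registered with the
#'   direction field.
#' @param fat FA stopping threshold in `[0, 1]`.
#' @param flt_mm fiber length threshold (mm).
#' @param step_mm step size (mm).
#' @param seeds `n x 3` matrix of seed points (world mm).
#' @param max_angle_deg turning-angle stop (degrees).
#' @param max_steps per-direction step cap.
#' @return List with `streamlines` (list of `n x 3` matrices), `seed_index`
#'   (which seed produced each), and `survived` (logical per seed).
#' @export
track_at_threshold <- function(direction_field, fa_volume, fat, flt_mm = 30,
                               step_mm = 1, seeds, max_angle_deg = 60,
                               max_steps = 2000L) {
  stopifnot(inherits(fa_volume, "volume_grid"))
  seeds <- as_point_matrix(seeds)
  n <- nrow(seeds)
  dirs <- list(direction_field[, , , 1L], direction_field[, , , 2L],
               direction_field[, , , 3L])
  cos_stop <- cos(max_angle_deg * pi / 180)
  eps <- 1e-6
  # a straight path cannot exceed the volume diagonal; cap storage there
  diag_mm <- sqrt(sum((fa_volume$shape * trk_voxel_size(fa_volume$affine))^2))
  max_steps <- min(max_steps, as.integer(ceiling(diag_mm / step_mm)) + 2L)

  interp_dir <- function(pts) {
    vox <- world_to_voxel(pts, fa_volume)
    cbind(interp_trilinear(dirs[[1L]], vox),
          interp_trilinear(dirs[[2L]], vox),
          interp_trilinear(dirs[[3L]], vox))
  }

  v0 <- interp_dir(seeds)
  nrm0 <- sqrt(rowSums(v0^2))
  fa0 <- sample_fa_along(seeds, fa_volume)
  alive0 <- nrm0 > eps & fa0 >= fat - 1e-12
  v0 <- v0 / pmax(nrm0, eps)

  march <- function(sign_dir) {
    pts <- vector("list", n)
    P <- seeds
    D <- sign_dir * v0
    active <- which(alive0)
    nsteps <- integer(n)
    path <- array(NA_real_, dim = c(max_steps, n, 3L))
    step <- 0L
    while (length(active) > 0L && step < max_steps) {
      step <- step + 1L
      Pn <- P[active, , drop = FALSE] + step_mm * D[active, , drop = FALSE]
      vox <- world_to_voxel(Pn, fa_volume)
      d <- fa_volume$shape
      inside <- vox[, 1L] >= 0 & vox[, 1L] <= d[1L] - 1 &
        vox[, 2L] >= 0 & vox[, 2L] <= d[2L] - 1 &
        vox[, 3L] >= 0 & vox[, 3L] <= d[3L] - 1
      fa_n <- interp_trilinear(fa_volume$data, vox)
      ok <- inside & fa_n >= fat - 1e-12
      if (any(ok)) {
        acc <- active[ok]
        path[step, acc, ] <- Pn[ok, , drop = FALSE]
        nsteps[acc] <- step
        P[acc, ] <- Pn[ok, , drop = FALSE]
        v <- interp_dir(Pn[ok, , drop = FALSE])
        nrm <- sqrt(rowSums(v^2))
        flip <- rowSums(v * D[acc, , drop = FALSE]) < 0
        v[flip, ] <- -v[flip, , drop = FALSE]
        vhat <- v / pmax(nrm, eps)
        cosang <- rowSums(vhat * D[acc, , drop = FALSE])
        go_on <- nrm > eps & cosang >= cos_stop
        D[acc[go_on], ] <- vhat[go_on, , drop = FALSE]
        active <- acc[go_on]
      } else {
        active <- integer(0)
      }
    }
    list(path = path, nsteps = nsteps)
  }

  fwd <- march(1)
  bwd <- march(-1)

  streamlines <- list()
  seed_index <- integer(0)
  survived <- logical(n)
  for (i in which(alive0)) {
    kf <- fwd$nsteps[i]
    kb <- bwd$nsteps[i]
    npts <- kf + kb + 1L
    if (npts < 2L) next
    pts <- matrix(NA_real_, npts, 3L)
    if (kb > 0L) pts[seq_len(kb), ] <- bwd$path[kb:1, i, ]
    pts[kb + 1L, ] <- seeds[i, ]
    if (kf > 0L) pts[kb + 1L + seq_len(kf), ] <- fwd$path[seq_len(kf), i, ]
    if ((npts - 1L) * step_mm >= flt_mm - 1e-9) {
      streamlines[[length(streamlines) + 1L]] <- pts
      seed_index <- c(seed_index, i)
      survived[i] <- TRUE
    }
  }
  list(streamlines = streamlines, seed_index = seed_index, survived = survived)
}

#' Per-seed fa_max by literal repeated-threshold tracking (oracle)
#'
#' Runs [track_at_threshold()] at every grid threshold from 0 upward; a
#' seed's `fa_max` is the largest threshold at which it still yields a
#' surviving streamline (length >= `flt_mm`).  This is the literal
#' incremental procedure; it exists as the independent reference for
#' [famax_by_sweep()] and is only practical on phantom-sized inputs.
#'
#' @inheritParams track_at_threshold
#' @param grid_step FA threshold grid (default 0.01).
#' @return List with `fa_max` (per-seed vector, NA where no threshold
#'   works), `fat_max` (their maximum), and `survival` (seeds x thresholds
#'   logical matrix, thresholds as columns).
#' @export
famax_by_retracking <- function(direction_field, fa_volume, seeds,
                                flt_mm = 30, step_mm = 1, grid_step = 0.01,
                                max_angle_deg = 60) {
  seeds <- as_point_matrix(seeds)
  ih_top <- as.integer(ceiling(max(fa_volume$data) / grid_step)) + 1L
  ths <- (0:ih_top) * grid_step
  survival <- matrix(FALSE, nrow(seeds), length(ths))
  for (k in seq_along(ths)) {
    res <- track_at_threshold(direction_field, fa_volume, fat = ths[k],
                              flt_mm = flt_mm, step_mm = step_mm,
                              seeds = seeds, max_angle_deg = max_angle_deg)
    survival[, k] <- res$survived
    if (!any(res$survived)) break
  }
  fa_max <- apply(survival, 1L, function(s) {
    w <- which(s)
    if (length(w) == 0L) NA_real_ else ths[max(w)]
  })
  colnames(survival) <- format(ths)
  list(fa_max = fa_max,
       fat_max = if (all(is.na(fa_max))) NA_real_ else max(fa_max, na.rm = TRUE),
       survival = survival)
}
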