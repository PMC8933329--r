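#' Construct a volume grid
#'
#' A `volume_grid` is the in-memory form of a 3-D NIfTI volume: a data array
#' plus a 4x4 voxel-to-world affine (RAS, mm).  Voxel indices are 0-based
#' throughout the package; the affine maps 0-based voxel indices to world
#' coordinates in mm, the NIfTI convention.
#'
#' @param data 3-D numeric array (scalar FA in `[0, 1]`, or non-negative
#'   integer labels with 0 reserved for background).
#' @param affine invertible 4x4 voxel-to-world matrix.
#' @param kind `"fa"` or `"label"`; controls validation.
#' @return An object of class `volume_grid` with elements `data`, `affine`,
#'   `shape` and `kind`.
#' @export
volume_grid <- function(data, affine, kind = c("fa", "label")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) {
    stop("volume data must be a 3-D array, got ", length(dim(data)), " dims")
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) stop("affine is not invertible")
  vol <- structure(
    list(data = data, affine = affine, shape = dim(data), kind = kind),
    class = "volume_grid"
  )
  validate_volume(vol)
  vol
}

validate_volume <- function(vol) {
  if (vol$kind == "fa") {
    bad <- which(vol$data < 0 | vol$data > 1 | !is.finite(vol$data))
    if (length(bad) > 0L) {
      idx <- arrayInd(bad[1L], vol$shape) - 1L
      stop(sprintf(
        "FA volume has %d value(s) outside [0, 1]; first at voxel (%d, %d, %d): %g",
        length(bad), idx[1L], idx[2L], idx[3L], vol$data[bad[1L]]
      ))
    }
  } else {
    if (any(vol$data < 0) || any(vol$data != round(vol$data))) {
      stop("label volume must contain non-negative integers")
    }
  }
  invisible(vol)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %s, %d x %d x %d voxels\n", x$kind,
    x$shape[1L], x$shape[2L], x$shape[3L]
  ))
  invisible(x)
}

#' Read a 3-D NIfTI volume
#'
#' The affine is taken from the best available header transform (sform, then
#' qform); data orientation is left untouched.
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param kind `"fa"` or `"label"`.  A 4-D file is an error for a label
#'   volume; FA values outside `[0, 1]` are a validation error naming the
#'   offending voxel.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, kind = c("fa", "label")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- array(img, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop(sprintf("expected a 3-D volume, got %d-D in %s", length(d), path))
  }
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  data <- array(as.vector(img), dim = d)
  if (kind == "label") storage.mode(data) <- "integer"
  volume_grid(data, affine, kind)
}

#' Write a volume grid to NIfTI-1
#'
#' @param vol a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' World-to-voxel and voxel-to-world coordinate maps
#'
#' Points are `n x 3` matrices of world coordinates (RAS mm) or continuous
#' 0-based voxel indices.
#'
#' @param points `n x 3` matrix.
#' @param vol a [volume_grid()] (its affine is used).
#' @return `n x 3` matrix in the other frame.
#' @export
world_to_voxel <- function(points, vol) {
  points <- as_point_matrix(points)
  inv <- solve(vol$affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(points, vol) {
  points <- as_point_matrix(points)
  h <- cbind(points, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  points
}

#' Trilinear interpolation at continuous voxel coordinates
#'
#' Out-of-bounds points evaluate to 0 by definition (not an error).
#'
#' @param data 3-D array.
#' @param vox `n x 3` continuous 0-based voxel coordinates.
#' @return Numeric vector of length `n`.
#' @keywords internal
interp_trilinear <- function(data, vox) {
  n <- nrow(vox)
  d <- dim(data)
  out <- numeric(n)
  inside <- vox[, 1L] >= 0 & vox[, 1L] <= d[1L] - 1 &
    vox[, 2L] >= 0 & vox[, 2L] <= d[2L] - 1 &
    vox[, 3L] >= 0 & vox[, 3L] <= d[3L] - 1
  if (!any(inside)) return(out)
  v <- vox[inside, , drop = FALSE]
  i0 <- floor(v)
  f <- v - i0
  # upper corner clamped so points on the far face keep weight on the face
  i1 <- pmin(i0 + 1, matrix(rep(d - 1, each = nrow(v)), ncol = 3L))
  i0 <- pmin(i0, i1)
  g0 <- 1 - f
  at <- function(ix, iy, iz) {
    data[cbind(ix + 1L, iy + 1L, iz + 1L)]
  }
  val <-
    at(i0[, 1], i0[, 2], i0[, 3]) * g0[, 1] * g0[, 2] * g0[, 3] +
    at(i1[, 1], i0[, 2], i0[, 3]) * f[, 1] * g0[, 2] * g0[, 3] +
    at(i0[, 1], i1[, 2], i0[, 3]) * g0[, 1] * f[, 2] * g0[, 3] +
    at(i0[, 1], i0[, 2], i1[, 3]) * g0[, 1] * g0[, 2] * f[, 3] +
    at(i1[, 1], i1[, 2], i0[, 3]) * f[, 1] * f[, 2] * g0[, 3] +
    at(i1[, 1], i0[, 2], i1[, 3]) * f[, 1] * g0[, 2] * f[, 3] +
    at(i0[, 1], i1[, 2], i1[, 3]) * g0[, 1] * f[, 2] * f[, 3] +
    at(i1[, 1], i1[, 2], i1[, 3]) * f[, 1] * f[, 2] * f[, 3]
  out[inside] <- val
  out
}

#' Sample FA along a streamline
#'
#' Trilinear interpolation of the FA volume at each streamline point after
#' the world-to-voxel map; points outside the volume get FA 0.
#'
#' @param streamline `n x 3` matrix of world-mm points.
#' @param fa_volume a [volume_grid()] of kind `"fa"`.
#' @return Numeric vector, one FA value per point.
#' @export
sample_fa_along <- function(streamline, fa_volume) {
  stopifnot(inherits(fa_volume, "volume_grid"))
  vox <- world_to_voxel(streamline, fa_volume)
  interp_trilinear(fa_volume$data, vox)
}

#' Nearest-voxel label lookup at world coordinates
#'
#' @param points `n x 3` world-mm matrix.
#' @param label_volume a [volume_grid()] of kind `"label"`.
#' @return Integer labels; 0 for background or out-of-bounds points.
#' @export
labels_at <- function(points, label_volume) {
  vox <- round(world_to_voxel(points, label_volume))
  d <- label_volume$shape
  n <- nrow(vox)
  out <- integer(n)
  inside <- vox[, 1L] >= 0 & vox[, 1L] < d[1L] &
    vox[, 2L] >= 0 & vox[, 2L] < d[2L] &
    vox[, 3L] >= 0 & vox[, 3L] < d[3L]
  if (any(inside)) {
    idx <- vox[inside, , drop = FALSE] + 1
    out[inside] <- label_volume$data[cbind(idx[, 1L], idx[, 2L], idx[, 3L])]
  }
  out
}

#' Check that two volumes share grid and affine
#'
#' Inputs are expected pre-co-registered; a shape or affine mismatch between
#' the FA and label volumes is a hard error, not something the package tries
#' to fix by resampling.
#'
#' @param a,b two [volume_grid()] objects.
#' @return `TRUE`, invisibly, or an error.
#' @export
check_coregistered <- function(a, b) {
  if (!all(a$shape == b$shape)) {
    stop("volumes are not co-registered: shapes differ (",
         paste(a$shape, collapse = "x"), " vs ",
         paste(b$shape, collapse = "x"), ")")
  }
  if (max(abs(a$affine - b$affine)) > 1e-4) {
    stop("volumes are not co-registered: affines differ")
  }
  invisible(TRUE)
}
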