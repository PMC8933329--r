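#' Read streamlines from a TCK or TRK file
#'
#' Streamlines are returned as a list of `n x 3` matrices of world
#' coordinates (RAS mm).  TCK stores world mm natively; TRK stores
#' "voxel-mm" coordinates (corner-origin voxel indices scaled by voxel size)
#' which are converted through the header's voxel-to-world transform.  A file
#' with zero fibers yields an empty list, not an error.
#'
#' @param path file ending in `.tck` or `.trk`.
#' @return List of `n x 3` double matrices, each with at least 2 rows.
#' @export
read_streamlines <- function(path) {
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
    tck = read_tck(path),
    trk = read_trk(path),
    stop("unsupported streamline format: .", ext, " (expected .tck or .trk)")
  )
  bad <- which(vapply(out, nrow, 1L) < 2L)
  if (length(bad) > 0L) out <- out[-bad]
  out
}

#' Write streamlines to a TCK or TRK file
#'
#' @param streamlines list of `n x 3` world-mm matrices.
#' @param path output file ending in `.tck` or `.trk`.
#' @param reference a [volume_grid()]; required for TRK, whose header embeds
#'   the voxel grid and voxel-to-world transform.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(streamlines, path, reference = NULL) {
  streamlines <- lapply(streamlines, as_point_matrix)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tck = write_tck(streamlines, path),
    trk = {
      if (is.null(reference)) stop("TRK output needs a reference volume_grid")
      write_trk(streamlines, path, reference)
    },
    stop("unsupported streamline format: .", ext)
  )
  invisible(path)
}

# --- TCK (MRtrix tracks): text header, Float32LE triplets, ----------------
# NaN-triplet track separator, Inf-triplet end-of-file sentinel.

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks")) {
    stop("malformed TCK header: first line is not 'mrtrix tracks'")
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed TCK header: missing END line")
    if (identical(trimws(line), "END")) break
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1L]]
    if (length(kv) == 2L) fields[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  datatype <- fields[["datatype"]]
  if (is.null(datatype)) stop("malformed TCK header: missing 'datatype' field")
  endian <- if (grepl("LE$", datatype)) "little" else "big"
  if (!grepl("^Float32", datatype)) {
    stop("malformed TCK header: unsupported 'datatype' ", datatype)
  }
  offs <- fields[["file"]]
  if (is.null(offs)) stop("malformed TCK header: missing 'file' field")
  offset <- as.numeric(sub("^\\.\\s+", "", offs))
  if (!is.finite(offset)) stop("malformed TCK header: unparseable 'file' offset")
  seek(con, where = offset, origin = "start")
  raw_n <- file.size(path) - offset
  vals <- readBin(con, "numeric", n = raw_n %/% 4L, size = 4L, endian = endian)
  split_tck_values(vals)
}

split_tck_values <- function(vals) {
  if (length(vals) %% 3L != 0L) stop("malformed TCK data: not float triplets")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  is_sep <- is.nan(m[, 1L])
  is_end <- is.infinite(m[, 1L])
  end_at <- which(is_end)
  if (length(end_at) > 0L) {
    keep <- seq_len(end_at[1L] - 1L)
    m <- m[keep, , drop = FALSE]
    is_sep <- is_sep[keep]
  }
  if (nrow(m) == 0L) return(list())
  grp <- cumsum(is_sep)
  out <- lapply(split(seq_len(nrow(m))[!is_sep], grp[!is_sep]), function(i) {
    m[i, , drop = FALSE]
  })
  names(out) <- NULL
  out[vapply(out, nrow, 1L) > 0L]
}

write_tck <- function(streamlines, path) {
  n <- length(streamlines)
  # the 'file: . <offset>' line depends on its own length; iterate to fixpoint
  offset <- 0L
  repeat {
    hdr <- paste0(
      "mrtrix tracks\n",
      "datatype: Float32LE\n",
      sprintf("count: %d\n", n),
      sprintf("file: . %d\n", offset),
      "END\n"
    )
    if (nchar(hdr, type = "bytes") == offset) break
    offset <- nchar(hdr, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

# --- TRK (TrackVis): fixed 1000-byte header, version 2 ---------------------
# Points are stored corner-origin: voxmm / voxel_size - 0.5 = 0-based voxel
# index, then mapped to world through vox_to_ras.

trk_voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", n = 6L)
  if (!identical(rawToChar(id[1:5]), "TRACK")) {
    stop("malformed TRK header: id_string is not 'TRACK'")
  }
  dim3 <- readBin(con, "integer", n = 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little") # origin, unused
  n_scalars <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  readBin(con, "raw", n = 200L) # scalar names
  n_props <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  readBin(con, "raw", n = 200L) # property names
  vox2ras <- matrix(
    readBin(con, "numeric", n = 16L, size = 4L, endian = "little"),
    nrow = 4L, byrow = TRUE
  )
  readBin(con, "raw", n = 444L + 4L + 4L + 24L + 2L + 6L) # reserved..invert
  n_count <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 1000L)) {
    stop("malformed TRK header: hdr_size is ", hdr_size, ", expected 1000")
  }
  if (version >= 2L && all(vox2ras == 0)) {
    stop("malformed TRK header: vox_to_ras transform is all zeros")
  }
  if (version < 2L) vox2ras <- diag(c(voxel_size, 1))
  if (any(voxel_size <= 0)) {
    stop("malformed TRK header: non-positive voxel_size")
  }
  out <- vector("list", max(n_count, 0L))
  k <- 0L
  repeat {
    npts <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric", n = npts * (3L + n_scalars),
                    size = 4L, endian = "little")
    if (n_props > 0L) readBin(con, "numeric", n = n_props, size = 4L,
                              endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2L, voxel_size, "/") - 0.5
    world <- cbind(vox, 1) %*% t(vox2ras)
    k <- k + 1L
    out[[k]] <- world[, 1:3, drop = FALSE]
  }
  out[seq_len(k)]
}

write_trk <- function(streamlines, path, reference) {
  stopifnot(inherits(reference, "volume_grid"))
  affine <- reference$affine
  voxel_size <- trk_voxel_size(affine)
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(reference$shape), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little") # origin
  writeBin(0L, con, size = 2L, endian = "little")          # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")          # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                  # reserved
  writeChar("RAS", con, nchars = 3L, eos = NULL)
  writeBin(raw(1L), con)
  writeBin(raw(4L + 24L + 2L + 6L), con)                    # pad2..invert
  writeBin(length(streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")           # version
  writeBin(1000L, con, size = 4L, endian = "little")        # hdr_size
  for (s in streamlines) {
    vox <- cbind(s, 1) %*% t(inv)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2L, voxel_size, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
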