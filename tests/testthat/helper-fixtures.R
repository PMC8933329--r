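# Shared fixtures and independent oracles.  Everything is generated in code;
# no binary fixtures on disk.

# Calibration-scale configuration: an 8-region parcellation whose regions
# sit at the corners of a 40 mm square in each hemisphere's y-z plane.
# Bundles run along square edges (no interior crossings) in ascending peak
# order, so no tube degrades another bundle's FA profile.  One bundle per
# hemisphere is marginal at the 25% VR cut (peak 0.14), one marginal at the
# 50% cut (peak 0.28), and one is the FAT_max anchor (peak 0.55), so subject
# networks vary stochastically at both thresholds.
tiny_bundles <- function(nf = 5L, jit = 0.02) {
  spec <- list(
    c(1L, 3L, 0.14), c(5L, 7L, 0.14),
    c(3L, 4L, 0.28), c(7L, 8L, 0.28),
    c(4L, 8L, 0.38), c(2L, 6L, 0.45),
    c(1L, 2L, 0.55), c(5L, 6L, 0.55)
  )
  lapply(spec, function(s) {
    list(region_a = as.integer(s[1L]), region_b = as.integer(s[2L]),
         n_fibers = nf, peak_fa = s[3L], fa_jitter = jit)
  })
}

tiny_config <- function(seed, n_per_group = 30L, ...) {
  synthetic_config(
    seed = seed, n_per_group = n_per_group,
    grid_shape = c(40L, 44L, 44L), voxel_mm = 2, n_regions = 8L,
    tube_radius_mm = 5, fibers_per_bundle = 5L, spacing_mm = 3,
    bundles = tiny_bundles(), ...
  )
}

# Tracking phantom for sweep-vs-retracking comparisons: three parallel
# straight bundles at 1 mm voxels (18 mm apart, so tubes never overlap),
# seeds at every suprathreshold voxel center.  The 4 mm radius keeps the
# trilinear support of jittered fiber points inside the tubes.
tracking_phantom <- function(seed = 42L, peaks = c(0.55, 0.45, 0.30)) {
  cfg <- synthetic_config(
    seed = seed, n_per_group = 2L,
    grid_shape = c(80L, 48L, 48L), voxel_mm = 1, n_regions = 8L,
    tube_radius_mm = 4, fa_jitter = 0.02,
    bundles = list(
      list(region_a = 1L, region_b = 5L, n_fibers = 5L,
           peak_fa = peaks[1L], fa_jitter = 0.02),
      list(region_a = 2L, region_b = 6L, n_fibers = 5L,
           peak_fa = peaks[2L], fa_jitter = 0.02),
      list(region_a = 3L, region_b = 7L, n_fibers = 5L,
           peak_fa = peaks[3L], fa_jitter = 0.02)
    )
  )
  parc <- make_parcellation(cfg)
  phantom <- suppressWarnings(make_phantom(cfg, parc))
  phantom
}

phantom_seeds <- function(phantom, fa_min = 0.15) {
  lin <- which(phantom$fa$data > fa_min)
  idx <- arrayInd(lin, phantom$fa$shape) - 1L
  voxel_to_world(idx, phantom$fa)
}

# Symmetric random 0/1 adjacency with zero diagonal.
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(stats::runif(sum(up)) < p)
  a <- a + t(a)
  dimnames(a) <- list(seq_len(n), seq_len(n))
  a
}

# --- definitional graph-metric oracles (BFS, not Floyd-Warshall) ----------

bfs_distances_from <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] > 0)
      new <- nb[is.infinite(d[nb])]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

eg_oracle <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  acc <- 0
  for (s in seq_len(n)) {
    d <- bfs_distances_from(adj, s)
    d[s] <- Inf
    acc <- acc + sum(1 / d)
  }
  acc / (n * (n - 1))
}

el_oracle <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0)
  acc <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) >= 2L) acc <- acc + eg_oracle(adj[nb, nb, drop = FALSE])
  }
  acc / n
}

ad_oracle <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0)
  mean(vapply(seq_len(n), function(i) sum(adj[i, ]), 0))
}

# Brute-force fa_max: try every grid threshold from high to low and check
# contiguous suprathreshold runs for one of arc length >= flt_mm.
famax_oracle <- function(fa, points, flt_mm = 30, grid_step = 0.01) {
  cl <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  for (ih in rev(0:100)) {
    t <- ih * grid_step
    ok <- fa >= t - 1e-12
    r <- rle(ok)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (j in which(r$values)) {
      if (cl[stops[j]] - cl[starts[j]] >= flt_mm - 1e-9) return(t)
    }
  }
  NA_real_
}

# One-subject fiber set with hand-controllable FA profiles.
straight_fiber <- function(from, to, n_pts, fa) {
  pts <- cbind(seq(from[1], to[1], length.out = n_pts),
               seq(from[2], to[2], length.out = n_pts),
               seq(from[3], to[3], length.out = n_pts))
  fiber_record(pts, fa)
}
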