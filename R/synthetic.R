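#' Configuration for the synthetic phantom cohort
#'
#' Collects every knob of the generator: phantom geometry, bundle
#' specification, the two-group structure (left-hemisphere connection
#' deficit, tumor-size distributions, aphasia levels) and the
#' stimulation-mapping probabilities.  Defaults describe the emulated study
#' conditions: two groups of 30, a 90-region bilateral parcellation, bundle
#' peak FA anchored near 0.53 so the subject-level FAT_max lands in the
#' 0.53 +/- 0.07 range, tumor sizes 2.4 +/- 2.6 cm^3 (no aphasia, "NA")
#' versus 4.7 +/- 4.3 cm^3 (glioma-induced aphasia, "GIA"), positive
#' mapping regions rarer than negative ones (about 8-10 vs 15-17 of 45 left
#' regions), and a multiplicative left-hemisphere bundle keep-probability
#' (`deficit`) of 0.6 for the GIA group.
#'
#' @param seed integer root seed; every random draw flows from it.
#' @param n_per_group subjects per group (>= 2).
#' @param grid_shape 3 positive integers (voxels).
#' @param voxel_mm isotropic voxel size (mm).
#' @param n_regions even region count (half per hemisphere).
#' @param margin_vox background margin around the labeled blocks (voxels).
#' @param tube_radius_mm bundle tube radius (mm).
#' @param fa_background background FA level (kept below 0.1).
#' @param bundles list of bundle specs (`region_a`, `region_b`, `n_fibers`,
#'   `peak_fa`, `fa_jitter`), or `NULL` to derive a default set from the
#'   parcellation geometry.
#' @param peak_fa_ladder peak FA values cycled over the default bundles;
#'   anchored at 0.53 and descending so the two VR thresholds separate the
#'   bundle population.
#' @param fa_jitter half-width of the uniform per-voxel FA jitter in tubes.
#' @param fibers_per_bundle fibers simulated per (kept) bundle.
#' @param spacing_mm spacing of simulated fiber points (mm).
#' @param fiber_jitter_sd per-point wiggle of simulated fibers (mm).
#' @param fiber_offset_frac constant transverse fiber offset, as a fraction
#'   of the tube radius; kept small enough that trilinear FA sampling along
#'   a fiber stays inside the tube.
#' @param deficit keep-probability in (0, 1] for each left-hemisphere bundle
#'   in a GIA subject; 1 is the null configuration (no group effect).
#' @param tumor_mean,tumor_sd named (`NA`, `GIA`) means / sds of tumor size
#'   (cm^3); draws are truncated at 0.
#' @param pos_prob,neg_prob per-left-region probability of being a positive
#'   / negative mapping region.
#' @param endpoint_pos_prob,endpoint_neg_prob elevated probabilities for
#'   left regions that are bundle endpoints (language sites cluster on
#'   connected cortex, and they give the mapping-region networks edges).
#' @param gia_pos_boost_n number of left regions whose positive-mapping
#'   probability is elevated in the GIA group.
#' @param gia_pos_boost_prob the elevated probability.
#' @param flt_mm fiber length threshold (mm).
#' @param grid_step FA threshold grid.
#' @param vr_thresholds the two VR thresholds (percent), strictly increasing.
#' @param min_fiber_count binarization cut: edges need strictly more fibers.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_per_group = 30L,
                             grid_shape = c(60L, 44L, 44L),
                             voxel_mm = 2,
                             n_regions = 90L,
                             margin_vox = 2L,
                             tube_radius_mm = 5,
                             fa_background = 0.05,
                             bundles = NULL,
                             peak_fa_ladder = c(0.55, 0.45, 0.38, 0.28, 0.22),
                             fa_jitter = 0.02,
                             fibers_per_bundle = 6L,
                             spacing_mm = 2,
                             fiber_jitter_sd = 0.3,
                             fiber_offset_frac = 0.3,
                             deficit = 0.6,
                             tumor_mean = c("NA" = 2.4, GIA = 4.7),
                             tumor_sd = c("NA" = 2.6, GIA = 4.3),
                             pos_prob = 0.19,
                             neg_prob = 0.37,
                             endpoint_pos_prob = 0.55,
                             endpoint_neg_prob = 0.75,
                             gia_pos_boost_n = 2L,
                             gia_pos_boost_prob = 0.4,
                             flt_mm = 30,
                             grid_step = 0.01,
                             vr_thresholds = c(25, 50),
                             min_fiber_count = 3L) {
  stopifnot(
    n_regions %% 2L == 0L, n_per_group >= 2L,
    deficit > 0, deficit <= 1,
    pos_prob >= 0, pos_prob <= 1, neg_prob >= 0, neg_prob <= 1,
    length(vr_thresholds) == 2L, diff(vr_thresholds) > 0,
    all(vr_thresholds > 0), all(vr_thresholds <= 100)
  )
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
         n_regions = as.integer(n_regions), margin_vox = as.integer(margin_vox),
         tube_radius_mm = tube_radius_mm, fa_background = fa_background,
         bundles = bundles, peak_fa_ladder = peak_fa_ladder,
         fa_jitter = fa_jitter,
         fibers_per_bundle = as.integer(fibers_per_bundle),
         spacing_mm = spacing_mm, fiber_jitter_sd = fiber_jitter_sd,
         fiber_offset_frac = fiber_offset_frac,
         deficit = deficit, tumor_mean = tumor_mean, tumor_sd = tumor_sd,
         pos_prob = pos_prob, neg_prob = neg_prob,
         endpoint_pos_prob = endpoint_pos_prob,
         endpoint_neg_prob = endpoint_neg_prob,
         gia_pos_boost_n = as.integer(gia_pos_boost_n),
         gia_pos_boost_prob = gia_pos_boost_prob,
         flt_mm = flt_mm, grid_step = grid_step,
         vr_thresholds = vr_thresholds,
         min_fiber_count = as.integer(min_fiber_count)),
    class = "synthetic_config"
  )
}

#' Null variant of a configuration
#'
#' No group effect anywhere: left bundles always kept, identical tumor-size
#' distributions, no elevated positive-mapping regions.  Used for type-I
#' error calibration.
#'
#' @param config a [synthetic_config()].
#' @return Modified configuration.
#' @export
null_config <- function(config) {
  config$deficit <- 1
  config$tumor_mean[] <- mean(config$tumor_mean)
  config$tumor_sd[] <- mean(config$tumor_sd)
  config$gia_pos_boost_n <- 0L
  config
}

derive_seed <- function(root, i) {
  as.integer((as.double(root) * 1000003 + 7919 * as.double(i)) %% 2147483629)
}

split_axis <- function(n, k) {
  cuts <- round(seq(0, n, length.out = k + 1L))
  lengths <- diff(cuts)
  if (any(lengths < 1L)) stop("infeasible packing: axis of ", n,
                              " voxels cannot hold ", k, " blocks")
  cuts
}

factor_triple <- function(h) {
  best <- c(h, 1L, 1L)
  best_score <- h
  for (a in seq_len(h)) {
    if (h %% a != 0L) next
    hb <- h %/% a
    for (b in seq_len(hb)) {
      if (hb %% b != 0L) next
      f <- sort(c(a, b, hb %/% b), decreasing = TRUE)
      score <- f[1L] / f[3L]
      if (score < best_score) {
        best <- f
        best_score <- score
      }
    }
  }
  best
}

#' Build a block parcellation
#'
#' Splits the volume at the world-x midline into two hemispheres and tiles
#' the inner box of each with `n_regions / 2` contiguous rectangular blocks
#' (an AAL-style template at phantom scale).  The affine centers the grid on
#' the origin, so left-hemisphere voxels have world x < 0.
#'
#' @param config a [synthetic_config()].
#' @return A `parcellation`: list with `volume` (label [volume_grid()]) and
#'   `regions` (data frame `id`, `name`, `hemisphere`).
#' @export
make_parcellation <- function(config) {
  gs <- config$grid_shape
  v <- config$voxel_mm
  m <- config$margin_vox
  h <- config$n_regions %/% 2L
  if (gs[1L] %% 2L != 0L) stop("grid x extent must be even (midline split)")
  half_x <- gs[1L] %/% 2L
  labels <- array(0L, dim = gs)
  # order the within-half factor triple to favor y/z so blocks spread over
  # the long axes available to 30+ mm bundles
  inner <- c(half_x - 2L * m, gs[2L] - 2L * m, gs[3L] - 2L * m)
  if (any(inner < 1L)) stop("infeasible packing: margins exceed the grid")
  f <- factor_triple(h)
  ord <- order(inner, decreasing = TRUE)
  k <- integer(3L)
  k[ord] <- f[seq_len(3L)]
  cx <- split_axis(inner[1L], k[1L])
  cy <- split_axis(inner[2L], k[2L])
  cz <- split_axis(inner[3L], k[3L])
  fill_half <- function(labels, x0, id0) {
    id <- id0
    for (iz in seq_len(k[3L])) for (iy in seq_len(k[2L])) {
      for (ix in seq_len(k[1L])) {
        xs <- x0 + m + (cx[ix] + 1L):cx[ix + 1L]
        ys <- m + (cy[iy] + 1L):cy[iy + 1L]
        zs <- m + (cz[iz] + 1L):cz[iz + 1L]
        labels[xs, ys, zs] <- id
        id <- id + 1L
      }
    }
    labels
  }
  labels <- fill_half(labels, 0L, 1L)
  labels <- fill_half(labels, half_x, h + 1L)
  affine <- diag(c(v, v, v, 1))
  affine[1:3, 4L] <- -(gs - 1) * v / 2
  vol <- volume_grid(labels, affine, kind = "label")
  regions <- data.frame(
    id = seq_len(config$n_regions),
    name = c(sprintf("L%02d", seq_len(h)), sprintf("R%02d", seq_len(h))),
    hemisphere = rep(c("L", "R"), each = h),
    stringsAsFactors = FALSE
  )
  parc <- structure(list(volume = vol, regions = regions),
                    class = "parcellation")
  cen <- region_centroids(parc)
  hemi <- ifelse(cen[, 1L] < 0, "L", "R")
  if (!identical(unname(hemi), regions$hemisphere)) {
    stop("internal error: block centroids disagree with hemisphere labels")
  }
  parc
}

#' Region centroids in world mm
#'
#' @param parcellation a `parcellation`.
#' @return `n x 3` matrix, rownames = region ids.
#' @export
region_centroids <- function(parcellation) {
  lab <- parcellation$volume$data
  ids <- parcellation$regions$id
  idx <- which(lab > 0L, arr.ind = TRUE)
  labv <- lab[lab > 0L]
  cen <- t(vapply(ids, function(id) {
    colMeans(idx[labv == id, , drop = FALSE]) - 1
  }, numeric(3L)))
  world <- voxel_to_world(cen, parcellation$volume)
  rownames(world) <- ids
  world
}

#' Default bundle specification from parcellation geometry
#'
#' Deterministically places bundles whose straight tubes comfortably exceed
#' the fiber length threshold.  Per hemisphere it first seeds a triangle
#' motif — the farthest region pair (A, B) plus the region C maximizing its
#' smaller distance to A and B, when all three legs are long enough — so the
#' binarized networks have connected neighborhoods and a nonzero local
#' efficiency, then adds further far-apart pairs greedily (regions may
#' recur, pairs do not).  Interhemispheric pairs follow the same greedy
#' rule.  Peak FA values cycle through `peak_fa_ladder`, anchoring the
#' first left and right bundles at the top of the ladder.
#'
#' @param parcellation a `parcellation`.
#' @param config a [synthetic_config()].
#' @param n_left,n_right,n_inter bundles per compartment.
#' @return List of bundle specs.
#' @export
default_bundle_spec <- function(parcellation, config, n_left = 5L,
                                n_right = 5L, n_inter = 2L) {
  cen <- region_centroids(parcellation)
  ids <- parcellation$regions$id
  hemi <- parcellation$regions$hemisphere
  min_sep <- config$flt_mm + 6
  dist_ij <- function(a, b) {
    sqrt(sum((cen[as.character(a), ] - cen[as.character(b), ])^2))
  }
  greedy_pairs <- function(cand_a, cand_b, n_want, seen = character(0)) {
    pairs <- expand.grid(a = cand_a, b = cand_b)
    pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
    d <- sqrt(rowSums((cen[as.character(pairs$a), , drop = FALSE] -
                       cen[as.character(pairs$b), , drop = FALSE])^2))
    ord <- order(-d)
    out <- list()
    for (i in ord) {
      if (d[i] < min_sep) break
      key <- paste(pairs$a[i], pairs$b[i])
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- c(pairs$a[i], pairs$b[i])
      if (length(out) >= n_want) break
    }
    out
  }
  hemi_pairs <- function(cand, n_want) {
    if (n_want < 1L) return(list())
    first <- greedy_pairs(cand, cand, 1L)
    if (length(first) == 0L) {
      stop("parcellation too small to place bundles >= ", min_sep, " mm long")
    }
    a <- first[[1L]][1L]; b <- first[[1L]][2L]
    out <- first
    rest <- setdiff(cand, c(a, b))
    if (n_want >= 3L && length(rest) > 0L) {
      reach <- vapply(rest, function(cc) min(dist_ij(a, cc), dist_ij(b, cc)), 0)
      cc <- rest[which.max(reach)]
      if (max(reach) >= min_sep) {
        out <- c(out, list(sort(c(a, cc)), sort(c(b, cc))))
      }
    }
    seen <- vapply(out, function(p) paste(p[1L], p[2L]), "")
    more <- greedy_pairs(cand, cand, n_want - length(out), seen = seen)
    c(out, more)[seq_len(min(n_want, length(out) + length(more)))]
  }
  left <- hemi_pairs(ids[hemi == "L"], n_left)
  right <- hemi_pairs(ids[hemi == "R"], n_right)
  inter <- greedy_pairs(ids[hemi == "L"], ids[hemi == "R"], n_inter)
  all_pairs <- c(left, right, inter)
  ladder <- config$peak_fa_ladder
  peaks <- c(ladder[1 + (seq_along(left) - 1L) %% length(ladder)],
             ladder[1 + (seq_along(right) - 1L) %% length(ladder)],
             ladder[1 + (seq_along(inter)) %% length(ladder)])
  lapply(seq_along(all_pairs), function(i) {
    list(region_a = all_pairs[[i]][1L], region_b = all_pairs[[i]][2L],
         n_fibers = config$fibers_per_bundle, peak_fa = peaks[i],
         fa_jitter = config$fa_jitter)
  })
}

#' Build the FA / direction phantom
#'
#' Each bundle is a straight tube of voxels joining its two region
#' centroids: inside a tube FA is `peak_fa` plus uniform per-voxel jitter
#' and the direction field is the tube tangent; outside, FA stays below 0.1
#' (background level plus small noise) and the direction field is zero.
#' Overlapping tubes are allowed (later bundles overwrite) with a warning.
#'
#' @param config a [synthetic_config()]; `config$bundles` may be `NULL`, in
#'   which case [default_bundle_spec()] is used.
#' @param parcellation a `parcellation` from [make_parcellation()].
#' @return List of class `phantom`: `fa` ([volume_grid()]), `directions`
#'   (4-D array), `bundles` (specs with centerline endpoints attached),
#'   `config`.
#' @export
make_phantom <- function(config, parcellation) {
  set.seed(derive_seed(config$seed, 104729L))
  bundles <- config$bundles
  if (is.null(bundles)) bundles <- default_bundle_spec(parcellation, config)
  gs <- config$grid_shape
  vol <- parcellation$volume
  cen <- region_centroids(parcellation)
  fa <- array(pmax(0.01, config$fa_background +
                     stats::runif(prod(gs), -0.02, 0.02)), dim = gs)
  dirs <- array(0, dim = c(gs, 3L))
  occupied <- array(FALSE, dim = gs)
  overlap_seen <- FALSE
  # voxel centers in world mm, computed once
  vox_idx <- as.matrix(expand.grid(x = 0:(gs[1L] - 1L), y = 0:(gs[2L] - 1L),
                                   z = 0:(gs[3L] - 1L)))
  vox_world <- voxel_to_world(vox_idx, vol)
  for (bi in seq_along(bundles)) {
    b <- bundles[[bi]]
    a_mm <- cen[as.character(b$region_a), ]
    b_mm <- cen[as.character(b$region_b), ]
    u <- b_mm - a_mm
    len <- sqrt(sum(u^2))
    u <- u / len
    rel <- sweep(vox_world, 2L, a_mm)
    t_par <- pmin(pmax(rel %*% u, 0), len)
    perp2 <- rowSums(rel^2) - t_par^2
    in_tube <- which(perp2 <= config$tube_radius_mm^2 + 1e-9)
    if (any(occupied[in_tube])) overlap_seen <- TRUE
    occupied[in_tube] <- TRUE
    fa[in_tube] <- pmin(1, pmax(0.01, b$peak_fa +
      stats::runif(length(in_tube), -b$fa_jitter, b$fa_jitter)))
    for (k in 1:3) {
      slice <- dirs[, , , k]
      slice[in_tube] <- u[k]
      dirs[, , , k] <- slice
    }
    bundles[[bi]]$start_mm <- a_mm
    bundles[[bi]]$end_mm <- b_mm
    bundles[[bi]]$length_mm <- len
  }
  if (overlap_seen) warning("bundle tubes overlap; later bundles overwrite")
  structure(
    list(fa = volume_grid(fa, vol$affine, kind = "fa"),
         directions = dirs, bundles = bundles, config = config),
    class = "phantom"
  )
}

#' Simulate streamlines for one subject
#'
#' Fibers are jittered copies of the bundle centerlines (a constant
#' transverse offset per fiber plus small per-point wiggle), with per-point
#' FA sampled from the phantom FA volume by trilinear interpolation.
#' Reproducible under a fixed seed.
#'
#' @param phantom a `phantom` from [make_phantom()].
#' @param seed integer seed for this subject's draws.
#' @param bundles bundle list to realize (default: all phantom bundles).
#' @param n_fibers fibers per bundle (default: each bundle's `n_fibers`).
#' @return List of [fiber_record()]s.
#' @export
make_streamlines <- function(phantom, seed, bundles = phantom$bundles,
                             n_fibers = NULL) {
  set.seed(seed)
  cfg <- phantom$config
  fibers <- list()
  for (b in bundles) {
    nf <- if (is.null(n_fibers)) b$n_fibers else n_fibers
    u <- (b$end_mm - b$start_mm) / b$length_mm
    basis <- orthonormal_basis(u)
    npts <- max(2L, as.integer(ceiling(b$length_mm / cfg$spacing_mm)) + 1L)
    t_seq <- seq(0, b$length_mm, length.out = npts)
    base <- outer(t_seq, u)
    base <- sweep(base, 2L, b$start_mm, "+")
    for (fi in seq_len(nf)) {
      r <- stats::runif(1L, 0, cfg$fiber_offset_frac * cfg$tube_radius_mm)
      th <- stats::runif(1L, 0, 2 * pi)
      offset <- r * (cos(th) * basis[, 1L] + sin(th) * basis[, 2L])
      wiggle <- matrix(stats::rnorm(npts * 3L, 0, cfg$fiber_jitter_sd),
                       npts, 3L)
      wiggle[c(1L, npts), ] <- 0  # endpoints stay in the end regions
      pts <- sweep(base, 2L, offset, "+") + wiggle
      fa <- sample_fa_along(pts, phantom$fa)
      fibers[[length(fibers) + 1L]] <- fiber_record(pts, fa)
    }
  }
  fibers
}

orthonormal_basis <- function(u) {
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2L] * e1[3L] - u[3L] * e1[2L],
          u[3L] * e1[1L] - u[1L] * e1[3L],
          u[1L] * e1[2L] - u[2L] * e1[1L])
  cbind(e1, e2)
}

#' Generate a two-group cohort
#'
#' Builds the parcellation and phantom once, then per subject: GIA subjects
#' drop each left-hemisphere bundle independently with keep-probability
#' `deficit`; tumor sizes are drawn per group (truncated at 0); the aphasia
#' level is 0 for every NA subject and, for GIA subjects, increases with the
#' fraction of left bundles lost (plus noise), so it correlates negatively
#' with realized left connectivity by construction; positive/negative
#' mapping region sets are drawn over left-hemisphere regions only, with the
#' positive probability elevated for `gia_pos_boost_n` designated regions in
#' the GIA group.
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_cohort`: `config`, `parcellation`,
#'   `phantom`, `cohort` (data frame of cohort records), `subjects` (list
#'   with per-subject `fibers` and bookkeeping).
#' @export
make_cohort <- function(config) {
  parc <- make_parcellation(config)
  if (is.null(config$bundles)) {
    config$bundles <- default_bundle_spec(parc, config)
  }
  phantom <- make_phantom(config, parc)
  bundles <- phantom$bundles
  hemi <- parcellation_hemi_map(parc)
  left_bundle <- vapply(bundles, function(b) {
    hemi[as.character(b$region_a)] == "L" && hemi[as.character(b$region_b)] == "L"
  }, TRUE)
  left_ids <- parc$regions$id[parc$regions$hemisphere == "L"]
  endpoint_ids <- unique(unlist(lapply(bundles[left_bundle], function(b) {
    c(b$region_a, b$region_b)
  })))
  boost <- integer(0)
  if (config$gia_pos_boost_n > 0L) {
    boost <- utils::tail(setdiff(left_ids, endpoint_ids),
                         config$gia_pos_boost_n)
    if (length(boost) < config$gia_pos_boost_n) {
      boost <- utils::tail(left_ids, config$gia_pos_boost_n)
    }
  }
  n <- config$n_per_group
  groups <- rep(c("NA", "GIA"), each = n)
  records <- vector("list", 2L * n)
  subjects <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    sid <- sprintf("S%03d", i)
    g <- groups[i]
    sseed <- derive_seed(config$seed, i)
    set.seed(sseed)
    keep <- rep(TRUE, length(bundles))
    if (g == "GIA" && config$deficit < 1) {
      keep[left_bundle] <- stats::runif(sum(left_bundle)) < config$deficit
    }
    kept_frac <- if (any(left_bundle)) {
      sum(keep & left_bundle) / sum(left_bundle)
    } else 1
    tumor <- max(0, stats::rnorm(1L, config$tumor_mean[[g]],
                                 config$tumor_sd[[g]]))
    level <- if (g == "NA") 0L else {
      as.integer(min(5, max(1, round(1 + 4 * (1 - kept_frac) +
                                       stats::rnorm(1L, 0, 0.7)))))
    }
    p_pos <- rep(config$pos_prob, length(left_ids))
    p_pos[left_ids %in% endpoint_ids] <- config$endpoint_pos_prob
    if (g == "GIA" && length(boost) > 0L) {
      p_pos[left_ids %in% boost] <- config$gia_pos_boost_prob
    }
    p_neg <- rep(config$neg_prob, length(left_ids))
    p_neg[left_ids %in% endpoint_ids] <- config$endpoint_neg_prob
    pos <- left_ids[stats::runif(length(left_ids)) < p_pos]
    neg <- left_ids[stats::runif(length(left_ids)) < p_neg]
    fibers <- make_streamlines(phantom, seed = derive_seed(sseed, 17L),
                               bundles = bundles[keep])
    records[[i]] <- data.frame(
      subject = sid, group = g, tumor_size = tumor, aphasia_level = level,
      kept_left_fraction = kept_frac, stringsAsFactors = FALSE
    )
    records[[i]]$pos_regions <- list(pos)
    records[[i]]$neg_regions <- list(neg)
    subjects[[i]] <- list(subject = sid, group = g, fibers = fibers,
                          kept_bundles = which(keep))
  }
  cohort <- do.call(rbind, records)
  structure(
    list(config = config, parcellation = parc, phantom = phantom,
         cohort = cohort, subjects = subjects),
    class = "synthetic_cohort"
  )
}

parcellation_hemi_map <- function(parcellation) {
  stats::setNames(parcellation$regions$hemisphere,
                  as.character(parcellation$regions$id))
}

#' Synthesize stimulation points from region sets
#'
#' Places `points_per_region` points near the centroid of every region in a
#' subject's positive and negative sets, emulating an exported
#' stimulation-site table so the point-to-region mapping stage can be
#' exercised end to end.
#'
#' @param cohort cohort data frame (with `pos_regions` / `neg_regions`).
#' @param parcellation a `parcellation`.
#' @param seed integer seed.
#' @param points_per_region points per mapped region.
#' @param spread_mm sd of the isotropic jitter around the centroid.
#' @return Data frame `subject`, `x`, `y`, `z`, `polarity`.
#' @export
make_stimulation_points <- function(cohort, parcellation, seed,
                                    points_per_region = 2L, spread_mm = 1.5) {
  set.seed(derive_seed(seed, 3571L))
  cen <- region_centroids(parcellation)
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    for (pol in c("POS", "NEG")) {
      ids <- if (pol == "POS") cohort$pos_regions[[i]] else cohort$neg_regions[[i]]
      for (id in ids) {
        pts <- matrix(rep(cen[as.character(id), ], points_per_region),
                      ncol = 3L, byrow = TRUE) +
          matrix(stats::rnorm(3L * points_per_region, 0, spread_mm),
                 ncol = 3L)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = cohort$subject[i], x = pts[, 1L], y = pts[, 2L],
          z = pts[, 3L], polarity = pol, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(subject = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), polarity = character(0)))
  }
  do.call(rbind, rows)
}
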