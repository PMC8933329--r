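test_that("parcellation splits regions evenly across hemispheres", {
  cfg <- synthetic_config(seed = 1L)
  parc <- make_parcellation(cfg)
  expect_equal(sum(parc$regions$hemisphere == "L"), 45L)
  expect_equal(sum(parc$regions$hemisphere == "R"), 45L)
  lab <- parc$volume$data
  expect_true(all(lab %in% c(0L, parc$regions$id)))
  expect_setequal(unique(lab[lab > 0L]), parc$regions$id)
  cen <- region_centroids(parc)
  expect_true(all(cen[parc$regions$hemisphere == "L", 1L] < 0))
  expect_true(all(cen[parc$regions$hemisphere == "R", 1L] > 0))

  toy <- tiny_config(seed = 1L, n_per_group = 2L)
  toy$n_regions <- 4L
  parc4 <- make_parcellation(toy)
  expect_setequal(unique(parc4$volume$data[parc4$volume$data > 0]), 1:4)
  expect_equal(parc4$regions$hemisphere, c("L", "L", "R", "R"))

  bad <- tiny_config(seed = 1L)
  bad$grid_shape <- c(6L, 4L, 4L)
  expect_error(make_parcellation(bad), "packing")
})

test_that("phantom tubes carry the requested FA and background stays low", {
  phantom <- tracking_phantom(seed = 5L)
  fa <- phantom$fa$data
  dirs <- phantom$directions
  in_tube <- sqrt(dirs[, , , 1L]^2 + dirs[, , , 2L]^2 + dirs[, , , 3L]^2) > 0.5
  expect_true(all(fa[!in_tube] < 0.1))
  expect_gt(max(fa[in_tube]), 0.5)
  # tube voxels of the anchor bundle sit near its peak
  anchor <- phantom$bundles[[1L]]
  expect_equal(anchor$peak_fa, 0.55)
  expect_gt(anchor$length_mm, 30)

  cfg0 <- synthetic_config(seed = 2L, grid_shape = c(40L, 20L, 20L),
                           voxel_mm = 2, n_regions = 4L, bundles = list())
  parc0 <- make_parcellation(cfg0)
  ph0 <- make_phantom(cfg0, parc0)
  expect_true(all(ph0$fa$data < 0.1))
})

test_that("simulated streamlines are reproducible and end in their regions", {
  phantom <- tracking_phantom(seed = 6L)
  parc <- make_parcellation(phantom$config)
  f1 <- make_streamlines(phantom, seed = 99L)
  f2 <- make_streamlines(phantom, seed = 99L)
  expect_identical(f1, f2)
  f3 <- make_streamlines(phantom, seed = 100L)
  expect_false(identical(f1, f3))
  expect_length(f1, sum(vapply(phantom$bundles, function(b) b$n_fibers, 0L)))
  k <- 0L
  for (b in phantom$bundles) {
    for (j in seq_len(b$n_fibers)) {
      k <- k + 1L
      ends <- f1[[k]]$points[c(1L, nrow(f1[[k]]$points)), , drop = FALSE]
      lab <- labels_at(ends, parc$volume)
      expect_setequal(lab, c(b$region_a, b$region_b))
    }
  }
  # per-fiber FA maxima stay in the jitter band of the bundle peak
  fam <- vapply(f1[1:5], famax_by_sweep, 0)
  expect_true(all(abs(fam - phantom$bundles[[1L]]$peak_fa) < 0.06))
})

test_that("cohorts are seed-stable with the constructed group structure", {
  cfg <- tiny_config(seed = 8L, n_per_group = 12L, deficit = 0.5)
  co1 <- suppressWarnings(make_cohort(cfg))
  co2 <- suppressWarnings(make_cohort(cfg))
  expect_identical(co1$cohort, co2$cohort)
  ch <- co1$cohort
  expect_equal(nrow(ch), 24L)
  expect_true(all(ch$aphasia_level[ch$group == "NA"] == 0L))
  expect_true(all(ch$aphasia_level[ch$group == "GIA"] >= 1L))
  expect_true(all(ch$tumor_size >= 0))
  left_ids <- co1$parcellation$regions$id[co1$parcellation$regions$hemisphere == "L"]
  expect_true(all(unlist(ch$pos_regions) %in% left_ids))
  expect_true(all(unlist(ch$neg_regions) %in% left_ids))
  # the GIA group drops left bundles: realized left connectivity is lower
  expect_lt(mean(ch$kept_left_fraction[ch$group == "GIA"]), 1)
  expect_equal(mean(ch$kept_left_fraction[ch$group == "NA"]), 1)
})

test_that("null configuration removes every group difference by construction", {
  cfg <- null_config(tiny_config(seed = 9L, n_per_group = 10L))
  expect_equal(cfg$deficit, 1)
  expect_equal(unname(diff(cfg$tumor_mean)), 0)
  co <- suppressWarnings(make_cohort(cfg))
  expect_true(all(co$cohort$kept_left_fraction == 1))
  # same per-subject fiber counts in both groups
  nf <- vapply(co$subjects, function(s) length(s$fibers), 0L)
  expect_equal(unique(nf), nf[1L])
})

test_that("stimulation points land in (or next to) their source regions", {
  cfg <- tiny_config(seed = 10L, n_per_group = 3L)
  co <- suppressWarnings(make_cohort(cfg))
  pts <- make_stimulation_points(co$cohort, co$parcellation, seed = 1L)
  expect_true(all(pts$polarity %in% c("POS", "NEG")))
  s1 <- pts[pts$subject == "S001" & pts$polarity == "POS", ]
  if (nrow(s1) > 0L) {
    m <- build_stimulation_map(s1, co$parcellation)
    expect_setequal(m$pos_regions, co$cohort$pos_regions[[1L]])
  }
})
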