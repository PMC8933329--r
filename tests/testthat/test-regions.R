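make_toy_parc <- function() {
  # two 4x8x8-voxel blocks (labels 1 left, 2 right) in a 16^3 grid, 1 mm
  lab <- array(0L, c(16, 16, 16))
  lab[3:6, 5:12, 5:12] <- 1L
  lab[11:14, 5:12, 5:12] <- 2L
  aff <- diag(4); aff[1:3, 4] <- -7.5
  structure(list(
    volume = volume_grid(lab, aff, kind = "label"),
    regions = data.frame(id = 1:2, name = c("L01", "R01"),
                         hemisphere = c("L", "R"), stringsAsFactors = FALSE)
  ), class = "parcellation")
}

test_that("points assign to containing voxels, with nearest-label fallback", {
  parc <- make_toy_parc()
  # world coordinates of voxel (4, 8, 8) (0-based) = (-3.5, 0.5, 0.5)
  expect_equal(assign_point(c(-3.5, 0.5, 0.5), parc), 1L)
  expect_equal(assign_point(c(3.5, 0.5, 0.5), parc), 2L)
  # background point 2 mm outside block 1's face falls back to it
  expect_equal(assign_point(c(-7.3, 0.5, 0.5), parc, search_radius_mm = 5), 1L)
  # fallback disabled: unassigned
  expect_equal(assign_point(c(-7.3, 0.5, 0.5), parc, search_radius_mm = 0), 0L)
  # far from any label: unassigned even with the default radius
  expect_equal(assign_point(c(-7.5, -7.5, -7.5), parc), 0L)
  # equidistant between both blocks: the smaller id wins
  expect_equal(assign_point(c(0, 0.5, 0.5), parc, search_radius_mm = 5), 1L)
  # fallback agrees with an exhaustive nearest-voxel search
  p <- c(-7.2, 3.2, -1.1)
  lin <- which(parc$volume$data > 0L)
  centers <- voxel_to_world(arrayInd(lin, dim(parc$volume$data)) - 1L,
                            parc$volume)
  d <- sqrt(rowSums(sweep(centers, 2L, p)^2))
  expect_equal(assign_point(p, parc, search_radius_mm = 5),
               parc$volume$data[lin[which.min(d)]])
})

test_that("stimulation maps separate POS/NEG and may share regions", {
  parc <- make_toy_parc()
  pts <- data.frame(
    x = c(-3.5, -3.5, 3.5), y = c(0.5, 0.5, 0.5), z = c(0.5, 0.5, 0.5),
    polarity = c("POS", "NEG", "NEG"), stringsAsFactors = FALSE
  )
  m <- build_stimulation_map(pts, parc)
  expect_equal(m$pos_regions, 1L)
  expect_setequal(m$neg_regions, c(1L, 2L))  # region 1 is in both sets
  expect_equal(m$n_pos, 1L)
  expect_equal(m$n_neg, 2L)
  m2 <- build_stimulation_map(pts, parc, pos_precedence = TRUE)
  expect_equal(m2$neg_regions, 2L)
  # unassigned points are dropped with a message
  pts2 <- rbind(pts, data.frame(x = -7.5, y = -7.5, z = -7.5,
                                polarity = "POS"))
  expect_message(m3 <- build_stimulation_map(pts2, parc), "unassigned")
  expect_equal(m3$n_dropped, 1L)
  expect_equal(m3$pos_regions, 1L)
  # empty table
  m4 <- build_stimulation_map(pts[0, ], parc)
  expect_equal(m4$n_pos + m4$n_neg, 0L)
})

test_that("intragroup proportions match a brute-force tally", {
  parc <- make_toy_parc()
  set.seed(41)
  cohort <- data.frame(subject = sprintf("S%02d", 1:30),
                       group = rep("NA", 30), stringsAsFactors = FALSE)
  cohort$pos_regions <- lapply(1:30, function(i) {
    if (i <= 28) 1L else integer(0)  # region 1 positive in 28/30
  })
  cohort$neg_regions <- lapply(1:30, function(i) {
    sample(1:2, sample(0:2, 1L))
  })
  pr <- intragroup_proportions(cohort, parc, highlight_min = 20L)
  row1 <- pr[pr$region == 1L & pr$polarity == "POS", ]
  expect_equal(row1$count, 28L)
  expect_equal(row1$proportion, 28 / 30)   # the 93.3% pattern
  expect_true(row1$highlighted)
  for (r in 1:2) {
    brute <- sum(vapply(cohort$neg_regions, function(s) r %in% s, TRUE))
    expect_equal(pr$count[pr$region == r & pr$polarity == "NEG"], brute)
  }
  expect_true(all(pr$proportion >= 0 & pr$proportion <= 1))
  # subject order does not matter
  pr2 <- intragroup_proportions(cohort[sample(1:30), ], parc,
                                highlight_min = 20L)
  expect_equal(pr2, pr)
})
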