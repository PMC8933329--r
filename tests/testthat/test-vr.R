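test_that("fa_max sweep handles the hand-worked profiles", {
  # points every 20 mm, FA 0.4 0.4 0.4 0.2: the three 0.4-points span 40 mm
  f1 <- straight_fiber(c(0, 0, 0), c(60, 0, 0), 4L, c(0.4, 0.4, 0.4, 0.2))
  expect_equal(famax_by_sweep(f1, flt_mm = 30), 0.40)
  # uniform FA 0.5 over 100 mm
  f2 <- straight_fiber(c(0, 0, 0), c(100, 0, 0), 11L, rep(0.5, 11))
  expect_equal(famax_by_sweep(f2, flt_mm = 30), 0.50)
  # 10 mm fiber can never span 30 mm
  f3 <- straight_fiber(c(0, 0, 0), c(10, 0, 0), 5L, rep(0.9, 5))
  expect_true(is.na(famax_by_sweep(f3, flt_mm = 30)))
  # the qualifying run need not touch the fiber's global FA maximum
  f4 <- straight_fiber(c(0, 0, 0), c(80, 0, 0), 9L,
                       c(0.2, 0.9, 0.2, 0.3, 0.3, 0.3, 0.3, 0.3, 0.2))
  expect_equal(famax_by_sweep(f4, flt_mm = 30), 0.30)
})

test_that("sweep equals brute force over all grid thresholds", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(4:40, 1L)
    span <- stats::runif(1, 15, 120)
    fa <- pmin(1, pmax(0, stats::runif(n, 0, 0.7) +
                         cumsum(stats::rnorm(n, 0, 0.05))))
    f <- straight_fiber(c(0, 0, 0), c(span, 0, 0), n, fa)
    expect_equal(famax_by_sweep(f, flt_mm = 30),
                 famax_oracle(fa, f$points, flt_mm = 30))
  }
})

test_that("tractogram drops sub-FLT fibers and sets FAT_max on the grid", {
  fibers <- list(
    straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0.52, 11)),
    straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0.26, 11)),
    straight_fiber(c(0, 0, 0), c(10, 0, 0), 5L, rep(0.9, 5))  # too short
  )
  tr <- subject_tractogram("S1", fibers, flt_mm = 30)
  expect_length(tr$fibers, 2L)
  expect_equal(tr$n_dropped_short, 1L)
  expect_equal(tr$fat_max, 0.52)
  expect_equal(round(tr$fat_max / 0.01) * 0.01, tr$fat_max)
  # fa_max never exceeds the pointwise FA maximum
  for (f in tr$fibers) expect_lte(f$fa_max, max(f$fa) + 1e-9)
})

test_that("VR formula, boundary inclusion and nestedness", {
  fibers <- list(
    straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0.52, 11)),
    straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0.26, 11)),
    straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0.13, 11))
  )
  tr <- compute_vr(subject_tractogram("S1", fibers, flt_mm = 30))
  vr <- vapply(tr$fibers, function(f) f$vr, 0)
  expect_equal(vr, c(100, 50, 25))
  # vr exactly 50 is included at threshold 50 (inclusive rule)
  expect_length(select_fibers(tr, 50), 2L)
  expect_length(select_fibers(tr, 25), 3L)
  expect_length(select_fibers(tr, 0), 3L)
  expect_length(select_fibers(tr, 100), 1L)
  # nestedness over a threshold ladder
  set.seed(37)
  fam <- lapply(1:30, function(i) {
    straight_fiber(c(0, 0, 0), c(60, 0, 0), 13L, stats::runif(13, 0.1, 0.6))
  })
  tr2 <- compute_vr(subject_tractogram("S2", fam, flt_mm = 30))
  prev <- length(tr2$fibers)
  for (t in c(10, 25, 50, 75, 100)) {
    cur <- length(select_fibers(tr2, t))
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_equal(max(vapply(tr2$fibers, function(f) f$vr, 0)), 100)
})

test_that("degenerate subjects are rejected or warned appropriately", {
  flat <- list(straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0, 11)))
  tr <- subject_tractogram("S0", flat, flt_mm = 30)
  expect_equal(tr$fat_max, 0)
  expect_error(compute_vr(tr), "degenerate")
})

test_that("famax formula examples for the VR ratio", {
  f1 <- straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0.25, 11))
  f2 <- straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0.50, 11))
  tr <- compute_vr(subject_tractogram("S1", list(f1, f2)))
  expect_equal(tr$fibers[[1L]]$vr, 50)
  f3 <- straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0.13, 11))
  f4 <- straight_fiber(c(0, 0, 0), c(50, 0, 0), 11L, rep(0.52, 11))
  tr2 <- compute_vr(subject_tractogram("S2", list(f3, f4)))
  expect_equal(tr2$fibers[[1L]]$vr, 25)
})
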