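test_that("ANCOVA t matches a closed-form normal-equation solve", {
  # fixed 6-subject dataset: value, group, covariate
  y <- c(3.1, 2.7, 3.4, 2.0, 1.8, 2.3)
  g <- c("A", "A", "A", "B", "B", "B")
  z <- c(1.2, 0.7, 1.9, 2.8, 2.1, 3.0)
  res <- ancova_group_test(y, g, z)
  X <- cbind(1, ifelse(g == "B", 1, 0), z)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% beta
  sigma2 <- sum(r^2) / (6 - 3)
  se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
  t_manual <- -beta[2] / se  # positive when group A sits higher
  expect_equal(res$statistic, t_manual, tolerance = 1e-8)
  expect_equal(res$f_value, t_manual^2, tolerance = 1e-8)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * stats::pt(-abs(t_manual), df = 3), tolerance = 1e-8)
  expect_equal(res$mean_a, mean(y[1:3]))
  expect_equal(res$mean_b, mean(y[4:6]))
})

test_that("ANCOVA reduces to the two-sample t when the covariate is inert", {
  set.seed(51)
  y <- c(rnorm(20, 1), rnorm(20, 1.6))
  g <- rep(c("A", "B"), each = 20)
  z <- 5 + rnorm(40, 0, 0.01)  # jittered, effectively inert covariate
  res <- ancova_group_test(y, g, z)
  tt <- stats::t.test(y[g == "A"], y[g == "B"], var.equal = TRUE)
  # an inert covariate still absorbs one noise df, so agreement is
  # approximate at n = 40, not exact
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 0.05)
  expect_equal(res$p, tt$p.value, tolerance = 0.15)
})

test_that("ANCOVA rejects degenerate designs", {
  y <- rnorm(10)
  g <- rep(c("A", "B"), each = 5)
  expect_error(ancova_group_test(y, g, as.numeric(g == "B")),
               "rank-deficient")
  expect_error(ancova_group_test(rep(1, 10), g, rnorm(10)), "constant")
  expect_error(ancova_group_test(y[1:4], g[c(1, 2, 6, 7)], rnorm(4)),
               "3 subjects")
})

test_that("chi-square equals the hand-computed sum of (O-E)^2/E", {
  tab <- rbind(c(10, 20), c(20, 10))
  res <- chi_square(tab)
  # expected counts are all 15; K = 4 * 25/15
  expect_equal(res$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p, stats::pchisq(4 * 25 / 15, 1, lower.tail = FALSE))
  manual <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  set.seed(53)
  for (rep in 1:20) {
    t2 <- matrix(sample(5:40, 4), 2, 2)
    expect_equal(chi_square(t2)$statistic, manual(t2), tolerance = 1e-12)
  }
  expect_error(chi_square(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("Mann-Whitney U matches exhaustive enumeration for 3+3", {
  a <- c(1.3, 2.9, 4.1)
  b <- c(0.7, 2.0, 3.5)
  res <- mann_whitney(a, b)
  u_manual <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(res$statistic, u_manual)
  # two-sided exact p by brute force over all 20 group assignments
  pool <- c(a, b)
  combs <- utils::combn(6, 3)
  u_null <- apply(combs, 2, function(ix) {
    sum(outer(pool[ix], pool[-ix], ">"))
  })
  dev <- abs(u_null - 4.5)
  p_manual <- mean(dev >= abs(u_manual - 4.5) - 1e-12)
  expect_equal(res$p, p_manual, tolerance = 1e-12)
  # identical groups: U = n1 n2 / 2 at p = 1
  resid <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(resid$statistic, 4.5)
  expect_equal(resid$p, 1)
})

test_that("t test and correlations behave on reference cases", {
  res <- independent_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(independent_t(rep(2, 5), rep(2, 5)), "zero")

  dec <- correlate_with_aphasia(c(5, 4, 3, 2, 1), 1:5)
  expect_equal(dec$statistic, -1)
  expect_error(correlate_with_aphasia(rep(1, 5), 1:5), "constant")
  # spearman equals pearson on rank-transformed data
  set.seed(57)
  x <- rnorm(30); y <- x + rnorm(30)
  sp <- correlate_with_aphasia(x, y, method = "spearman")
  pe <- stats::cor(rank(x), rank(y))
  expect_equal(sp$statistic, pe, tolerance = 1e-12)
})

test_that("BH adjustment equals the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  set.seed(59)
  p <- runif(25)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  # permutation invariance
  perm <- sample(25)
  expect_equal(fdr_adjust(p[perm]), adj[perm])
  # manual step-up
  o <- order(p, decreasing = TRUE)
  manual <- numeric(25)
  running <- 1
  for (k in seq_along(o)) {
    i <- o[k]
    rank_i <- 26 - k
    running <- min(running, p[i] * 25 / rank_i)
    manual[i] <- running
  }
  expect_equal(adj, manual, tolerance = 1e-12)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group and correlation tables cover kinds x metrics x blocks", {
  cfg <- tiny_config(seed = 61L, n_per_group = 8L)
  res <- suppressWarnings(run_cohort(cfg))
  expect_equal(nrow(res$comparison), 45L)
  expect_equal(nrow(res$correlation), 45L)
  expect_setequal(unique(res$comparison$kind),
                  c("whole", "left", "right", "pos", "neg"))
  expect_setequal(unique(res$comparison$block), c("vr25", "vr50", "diff"))
  expect_true(all(res$comparison$p_fdr >= res$comparison$p, na.rm = TRUE))
  expect_true(all(res$correlation$p >= 0 & res$correlation$p <= 1,
                  na.rm = TRUE))
  # missing subject metrics are a named error
  broken <- res$metrics[res$metrics$subject != "S003", ]
  expect_error(group_comparison_table(broken, res$cohort), "S003")
})
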