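test_that("closed forms: complete, star, path and empty graphs", {
  for (n in c(3, 4, 7)) {
    k <- matrix(1L, n, n); diag(k) <- 0L
    expect_equal(average_degree(k), n - 1)
    expect_equal(global_efficiency(k), 1)
    expect_equal(local_efficiency(k), 1)
  }
  k2 <- rbind(c(0L, 1L), c(1L, 0L))
  expect_equal(global_efficiency(k2), 1)
  expect_equal(local_efficiency(k2), 0)  # single-neighbor nodes contribute 0
  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L; star[2:5, 1] <- 1L
  expect_equal(local_efficiency(star), 0)  # hub neighborhood edgeless
  expect_equal(average_degree(star), 2 * 4 / 5)

  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(global_efficiency(path3), 5 / 6)  # pairs at d = 1, 1, 2

  empty <- matrix(0L, 4, 4)
  expect_equal(average_degree(empty), 0)
  expect_equal(global_efficiency(empty), 0)
  expect_equal(local_efficiency(empty), 0)

  tri <- matrix(1L, 3, 3); diag(tri) <- 0L
  expect_equal(local_efficiency(tri), 1)  # each neighborhood is an edge

  expect_equal(graph_metrics(matrix(0L, 1, 1)), list(ad = 0, eg = 0, el = 0))
  expect_equal(graph_metrics(matrix(numeric(0), 0, 0)),
               list(ad = 0, eg = 0, el = 0))
})

test_that("metrics equal definitional brute force on random graphs", {
  set.seed(11)
  for (rep in 1:220) {
    n <- sample(2:12, 1L)
    adj <- random_adjacency(n, stats::runif(1, 0.1, 0.9))
    expect_equal(average_degree(adj), ad_oracle(adj), tolerance = 1e-12)
    expect_equal(global_efficiency(adj), eg_oracle(adj), tolerance = 1e-12)
    expect_equal(local_efficiency(adj), el_oracle(adj), tolerance = 1e-12)
  }
})

test_that("shortest-path lengths agree with igraph", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:25) {
    adj <- random_adjacency(sample(3:20, 1L), stats::runif(1, 0.1, 0.6))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(shortest_path_lengths(adj)),
                 unname(igraph::distances(g)))
  }
})

test_that("adding edges never decreases AD or EG", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(4:12, 1L)
    a <- random_adjacency(n, stats::runif(1, 0.1, 0.5))
    b <- a
    off <- which(upper.tri(b) & b == 0L)
    if (length(off) == 0L) next
    add <- sample(off, min(length(off), sample(1:3, 1L)))
    b[add] <- 1L
    b[lower.tri(b)] <- t(b)[lower.tri(b)]
    expect_gte(average_degree(b), average_degree(a))
    expect_gte(global_efficiency(b), global_efficiency(a))
  }
})

test_that("submatrix induces subgraphs and validates ids", {
  adj <- random_adjacency(6, 0.5)
  sub <- submatrix(adj, c(2, 5, 6))
  expect_equal(dim(sub), c(3L, 3L))
  expect_equal(sub[1, 2], adj[2, 5])
  expect_equal(submatrix(adj, 1:6), adj)
  expect_equal(dim(submatrix(adj, 3)), c(1L, 1L))
  expect_equal(dim(submatrix(adj, integer(0))), c(0L, 0L))
  expect_error(submatrix(adj, c(1, 99)), "unknown node id")
})

test_that("binarization boundary follows the more-than-three rule", {
  counts <- rbind(c(0, 3, 4), c(3, 0, 7), c(4, 7, 0))
  adj <- binarize(counts, min_count = 3L)
  expect_equal(adj[1, 2], 0L)  # exactly 3 fibers: not connected
  expect_equal(adj[1, 3], 1L)  # 4 fibers: connected
  expect_equal(adj[2, 3], 1L)
  expect_true(all(adj == t(adj)) && all(diag(adj) == 0L))
  expect_equal(sum(binarize(matrix(0L, 4, 4))), 0L)
})

test_that("edge prevalence counts subjects and masks rare edges", {
  set.seed(23)
  adjs <- replicate(30, random_adjacency(5, 0.4), simplify = FALSE)
  gp <- group_edge_prevalence(adjs, min_subjects = 10L)
  brute <- matrix(0L, 5, 5)
  for (a in adjs) brute <- brute + a
  expect_equal(unname(gp$prevalence), unname(brute))
  expect_true(all(gp$masked[gp$prevalence < 10] == 0))
  expect_true(all(gp$masked[gp$prevalence >= 10] ==
                    gp$prevalence[gp$prevalence >= 10]))
})

test_that("diff metrics subtract high-threshold from low-threshold values", {
  lo <- list(ad = 7.635, eg = 0.537, el = 0.717)
  hi <- list(ad = 2.863, eg = 0.330, el = 0.367)
  d <- diff_metrics(lo, hi)
  expect_equal(d$ad_diff, 4.772)
  expect_equal(diff_metrics(lo, lo), list(ad_diff = 0, eg_diff = 0, el_diff = 0))
  # nested edge sets: ad and eg differences are non-negative
  set.seed(29)
  for (rep in 1:40) {
    b <- random_adjacency(8, 0.5)
    a <- b
    on <- which(upper.tri(a) & a == 1L)
    if (length(on) > 0L) {
      drop <- sample(on, sample(seq_along(on), 1L))
      a[drop] <- 0L
      a[lower.tri(a)] <- t(a)[lower.tri(a)]
    }
    d <- diff_metrics(graph_metrics(b), graph_metrics(a))  # a subset of b
    expect_gte(d$ad_diff, 0)
    expect_gte(d$eg_diff, -1e-12)
  }
})
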