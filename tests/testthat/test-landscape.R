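test_that("pair orientation takes the smaller MFPT as forward", {
  expect_identical(orient_pair(5, 5000),
                   list(forward = 5, reverse = 5000, swapped = FALSE,
                        tie = FALSE))
  expect_identical(orient_pair(5000, 5),
                   list(forward = 5, reverse = 5000, swapped = TRUE,
                        tie = FALSE))
  tie <- orient_pair(7, 7)
  expect_identical(c(tie$forward, tie$reverse), c(7, 7))
  expect_true(tie$tie)
  expect_error(orient_pair(-1, 5))
  expect_error(orient_pair(Inf, 5))
})

test_that("classification matches the threshold definitions", {
  expect_identical(classify_pair(5, 5000, 10, 1000), "directional")
  expect_identical(classify_pair(2000, 3000, 10, 1000), "separate")
  expect_identical(classify_pair(10, 20, 10, 1000), "neither")
  # boundary: forward exactly at the separation threshold counts as separate
  expect_identical(classify_pair(1000, 1000, 10, 1000), "separate")
  # invariant to argument order (orientation happens first)
  expect_identical(classify_pair(5000, 5, 10, 1000), "directional")
  # raising the separation threshold can only shrink the separate set
  set.seed(41)
  fwd <- 10^stats::runif(200, 0, 5)
  rev <- fwd * 10^stats::runif(200, 0, 3)
  seps <- c(1e2, 1e3, 1e4)
  counts <- vapply(seps, function(s) {
    sum(mapply(classify_pair, fwd, rev, 10, s) == "separate")
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("pair records orient and label every unordered pair once", {
  set.seed(43)
  net <- random_multiattractor_net(6, min_attractors = 3L)
  mm <- attractor_mfpt_matrix(net, 0.02)
  pr <- pair_records(mm)
  k <- nrow(mm$values)
  expect_identical(nrow(pr), k * (k - 1L) %/% 2L)
  expect_true(all(pr$forward <= pr$reverse))
  for (r in seq_len(nrow(pr))) {
    expect_identical(pr$forward[r],
                     min(mm$values[pr$attractor_i[r], pr$attractor_j[r]],
                         mm$values[pr$attractor_j[r], pr$attractor_i[r]]))
  }
})

test_that("density grids conserve mass above the diagonal", {
  g1 <- density_grid(5, 50)
  expect_identical(sum(g1$counts), 1)
  set.seed(44)
  fwd <- 10^stats::runif(300, 0, 4)
  rev <- fwd * 10^stats::runif(300, 0, 2)
  g <- density_grid(fwd, rev, breaks = seq(0, 7, length.out = 41))
  expect_identical(sum(g$counts), 300)
  # oriented pairs live on or above the diagonal
  expect_identical(sum(g$counts[lower.tri(g$counts)]), 0)
  expect_error(density_grid(c(1, -2), c(3, 4)), "positive")
})

test_that("normalized grid differences cancel exactly", {
  set.seed(45)
  br <- seq(0, 6, length.out = 41)
  f1 <- 10^stats::runif(100, 0, 3); r1 <- f1 * 2
  f2 <- 10^stats::runif(80, 1, 4); r2 <- f2 * 3
  a <- density_grid(f1, r1, breaks = br, normalize = TRUE)
  b <- density_grid(f2, r2, breaks = br, normalize = TRUE)
  expect_equal(sum(density_difference(a, a)$counts), 0, tolerance = 1e-15)
  expect_true(all(density_difference(a, a)$counts == 0))
  expect_lt(abs(sum(density_difference(a, b)$counts)), 1e-12)
  expect_error(density_difference(a, density_grid(f2, r2, breaks = br)),
               "normalized")
  b2 <- density_grid(f2, r2, breaks = seq(0, 5, length.out = 41),
                     normalize = TRUE)
  expect_error(density_difference(a, b2), "mismatched")
})

test_that("MFPT graphs prune exactly the edges above threshold", {
  set.seed(46)
  net <- random_multiattractor_net(6, min_attractors = 3L)
  mm <- attractor_mfpt_matrix(net, 0.02)
  g <- mfpt_graph(mm)
  k <- nrow(mm$values)
  expect_equal(igraph::vcount(g), k)
  expect_equal(igraph::ecount(g), k * (k - 1L))
  w <- igraph::E(g)$weight
  thr <- stats::median(w)
  gp <- prune_mfpt_graph(g, thr)
  expect_equal(igraph::vcount(gp), k)              # node set unchanged
  expect_equal(igraph::ecount(gp), sum(w <= thr))
  expect_true(all(igraph::E(gp)$weight <= thr))
  # extreme thresholds: identity and edgeless
  expect_equal(igraph::ecount(prune_mfpt_graph(g, Inf)), k * (k - 1L))
  expect_equal(igraph::ecount(prune_mfpt_graph(g, min(w) / 2)), 0)
})

test_that("mfpt_analysis bundles attractors, matrix and labelled pairs", {
  fit <- mfpt_analysis(toggle_network(), p_e = 0.05)
  expect_s3_class(fit, "mfpt_analysis")
  expect_identical(nrow(fit$pairs), 3L)
  expect_identical(fit$params$p_e, 0.05)
  expect_output(print(fit), "3 attractors")
  expect_output(print(summary(fit)), "basin sizes")
  expect_error(mfpt_analysis(constant_network(3)), "single attractor")
})

test_that("noisy simulation follows D when no flip occurs", {
  tg <- toggle_network()
  # p_e so small that 10 steps are almost surely flip-free
  tr <- simulate(tg, nsim = 4, seed = 1, from = 0L, p_e = 1e-9)
  expect_identical(tr, c(0L, 3L, 0L, 3L, 0L))
  a <- simulate(tg, nsim = 50, seed = 2, p_e = 0.3)
  b <- simulate(tg, nsim = 50, seed = 2, p_e = 0.3)
  expect_identical(a, b)
})
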