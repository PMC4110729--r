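test_that("noisy kernel matches the hand computation on the identity net", {
  tm <- transition_matrix(identity_network(), 0.1)
  expect_equal(tm$p, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2), tolerance = 1e-15)
  expect_error(transition_matrix(identity_network(), 0), "p_e")
  expect_error(transition_matrix(identity_network(), 1), "p_e")
})

test_that("noisy kernel equals the brute-force flip-mask enumeration", {
  for (fix in list(toggle_network(), constant_network(3),
                   generate_critical_rbn(4, 2L, seed = 13))) {
    for (p_e in c(0.01, 0.2)) {
      tm <- transition_matrix(fix, p_e)
      expect_equal(tm$p, brute_force_transition(fix, p_e), tolerance = 1e-14)
    }
  }
})

test_that("rows are stochastic and self-mass appears only at fixed points", {
  set.seed(31)
  for (rep in 1:5) {
    net <- generate_critical_rbn(sample(3:6, 1), 2L)
    tm <- transition_matrix(net, 0.05)
    expect_lt(max(abs(rowSums(tm$p) - 1)), 1e-12)
    expect_true(all(tm$p >= 0))
    Dm <- state_map(net)
    fixed <- which(Dm == seq_along(Dm) - 1L)
    expect_equal(diag(tm$p)[fixed], rep((1 - 0.05)^net$n, length(fixed)),
                 tolerance = 1e-15)
    expect_true(all(diag(tm$p)[setdiff(seq_along(Dm), fixed)] == 0))
  }
})

test_that("first-passage base case and recursion follow the definition", {
  tm <- transition_matrix(identity_network(), 0.1)
  expect_identical(first_passage_probability(tm, 0L, 1L, 1), tm$p[1, 2])
  expect_equal(first_passage_probability(tm, 0L, 1L, 2), 0.9 * 0.1,
               tolerance = 1e-15)
  expect_error(first_passage_probability(tm, 0L, 1L, 0), "k")
  # F_k is a probability distribution over k: nonnegative, mass -> 1
  tg <- transition_matrix(toggle_network(), 0.2)
  fk <- vapply(1:200, function(k) first_passage_probability(tg, 0L, 2L, k), 0)
  expect_true(all(fk >= 0))
  expect_true(all(diff(cumsum(fk)) >= 0))
  expect_lte(max(cumsum(fk)), 1 + 1e-12)
  expect_equal(sum(fk), 1, tolerance = 1e-6)
})

test_that("MFPT on the identity net equals the geometric mean 1/p_e", {
  for (p_e in c(0.1, 0.01)) {
    tm <- transition_matrix(identity_network(), p_e)
    expect_equal(mfpt_states(tm, 0L, 1L), 1 / p_e, tolerance = 1e-9)
  }
  tm <- transition_matrix(identity_network(), 0.1)
  expect_error(mfpt_states(tm, 0L, 0L), "disjoint")
  expect_error(mfpt_states(tm, integer(0), 1L), "nonempty")
})

test_that("linear solve, truncated series and Monte Carlo agree (toggle)", {
  tm <- transition_matrix(toggle_network(), 0.1)
  solve_val <- mfpt_states(tm, 2L, 1L)     # {01} -> {10}
  series_val <- mfpt_series_oracle(tm, 2L, 1L)
  expect_equal(solve_val, as.numeric(series_val), tolerance = 1e-6)
  expect_lt(attr(series_val, "error_bound"), 1e-8)
  set.seed(99)
  mc <- mfpt_monte_carlo(toggle_network(), 0.1, 2L, 1L, reps = 4000)
  expect_lt(abs(mc$mean - solve_val), 3 * mc$stderr)
  # truncation at K = 1 returns only the one-step mass
  expect_warning(k1 <- mfpt_series_oracle(tm, 2L, 1L, K = 1),
                 "truncated")
  expect_identical(as.numeric(k1), tm$p[3, 2])
})

test_that("Monte-Carlo runs are exactly reproducible under a seed", {
  set.seed(123)
  a <- mfpt_monte_carlo(toggle_network(), 0.1, 0L, 2L, reps = 200)
  set.seed(123)
  b <- mfpt_monte_carlo(toggle_network(), 0.1, 0L, 2L, reps = 200)
  expect_identical(a, b)
})

test_that("attractor MFPT matrix has the contracted shape and asymmetry", {
  mm <- attractor_mfpt_matrix(toggle_network(), 0.05)
  expect_identical(dim(mm$values), c(3L, 3L))
  expect_true(all(diag(mm$values) == 0))
  off <- mm$values[row(mm$values) != col(mm$values)]
  expect_true(all(is.finite(off) & off > 0))
  # random nets are generically asymmetric
  set.seed(17)
  net <- random_multiattractor_net(6, min_attractors = 3L)
  M <- attractor_mfpt_matrix(net, 0.02)$values
  expect_gt(max(abs(M - t(M))), 1e-6)
  expect_error(attractor_mfpt_matrix(constant_network(3), 0.05), "2 attractors")
})

test_that("lower noise never shortens attractor passage times", {
  set.seed(19)
  nets <- list(toggle_network(), random_multiattractor_net(5),
               random_multiattractor_net(6))
  for (net in nets) {
    hi <- attractor_mfpt_matrix(net, 0.05)$values
    lo <- attractor_mfpt_matrix(net, 0.01)$values
    off <- row(hi) != col(hi)
    expect_true(all(lo[off] >= hi[off] - 1e-9))
  }
})

test_that("the dense-matrix node cap is enforced", {
  net <- generate_critical_rbn(13, 2L, seed = 2)
  expect_error(transition_matrix(net, 0.05), "cap")
})
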