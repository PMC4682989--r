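test_that("node chains of small graphs match closed forms", {
  tri <- node_chain(triangle_net(c(a = 1L, b = 0L, c = 0L)))
  expect_equal(tri$P, matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3L, 3L),
               tolerance = 1e-12)
  expect_equal(tri$pi, rep(1 / 3, 3L), tolerance = 1e-12)
  expect_equal(tri$lambdas, c(1, -0.5, -0.5), tolerance = 1e-10)
  pth <- node_chain(path_net())
  expect_equal(pth$pi, c(1 / 4, 1 / 2, 1 / 4), tolerance = 1e-12)
  expect_error(node_chain(rds_network(rbind(c("a", "b"), c("c", "d")),
                                      c(a = 1, b = 0, c = 1, d = 0))),
               "disconnected")
})

test_that("chain invariants hold on all fixture chains", {
  chains <- list(
    node_chain(triangle_net(c(a = 1L, b = 0L, c = 0L))),
    node_chain(path_net()),
    table1_chain(spec_ex1()), table1_collapse(spec_ex1()),
    table1_chain(spec_ex2()), table1_collapse(spec_ex2()),
    node_chain(largest_component(
      realize_block_network(block_spec(E = 100, F = 100, H = 100,
                                       n_per_cell = 50L), seed = 2L))))
  for (ch in chains) {
    expect_lt(max(abs(as.vector(ch$pi %*% ch$P) - ch$pi)), 1e-10)
    expect_equal(sum(ch$pi), 1, tolerance = 1e-10)
    expect_equal(ch$lambdas[1L], 1, tolerance = 1e-10)
    expect_lte(max(abs(ch$lambdas)), 1 + 1e-10)
    expect_lt(abs(ch$alphas[1L]), 1e-10)      # mean-centering
    ystar <- ch$y - sum(ch$pi * ch$y)
    expect_equal(sum(ch$alphas[-1L]^2), sum(ch$pi * ystar^2),
                 tolerance = 1e-10)           # loadings carry the variance
  }
})

test_that("block chains reproduce the worked transition matrices", {
  ch1 <- table1_chain(spec_ex1())
  expect_equal(round(ch1$P, 3),
               matrix(c(.667, .333, 0, 0,
                        .333, .333, .333, 0,
                        0, .333, .333, .333,
                        0, 0, .333, .667), 4L, 4L, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(table1_collapse(spec_ex1())$P,
               matrix(c(5 / 6, 1 / 6, 1 / 6, 5 / 6), 2L, 2L, byrow = TRUE),
               tolerance = 1e-12)
  ch2 <- table1_chain(spec_ex2())
  expect_equal(round(ch2$P, 3),
               matrix(c(.952, .048, 0, 0,
                        .048, .476, .476, 0,
                        0, .476, .476, .048,
                        0, 0, .048, .952), 4L, 4L, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(table1_collapse(spec_ex2())$P[1L, 2L], 5 / 21, tolerance = 1e-12)
  # H = 0: no cross-Y mixing, chain reducible across Y and flagged
  ch0 <- table1_chain(block_spec(E = 10, F = 10, H = 0))
  expect_false(ch0$irreducible)
})

test_that("closed-form eigenvalues agree with numeric decomposition on a grid", {
  for (a in c(0.05, 0.2, 1 / 3, 0.45)) {
    for (b in c(0.05, 0.2, 1 / 3, 0.5)) {
      if (a + b > 1) next
      tot <- 1000
      sp <- block_spec(E = tot * (1 - a - b), F = tot * a, H = tot * b,
                       n_per_cell = 10L)
      cf <- table1_eigenvalues(sp)
      num <- sort(eigen(table1_chain(sp)$P, only.values = TRUE)$values,
                  decreasing = TRUE)
      expect_lt(max(abs(cf - num)), 1e-10)
      # second eigenvalue of the 4-state chain strictly exceeds the
      # collapse's 1 - b whenever a, b > 0: the VHE's chain mixes faster
      expect_gt(cf[2L], table1_collapse(sp)$lambdas[2L])
    }
  }
})

test_that("propagate applies matrix powers and converges to pi", {
  ch <- table1_chain(spec_ex1())
  p0 <- c(1, 0, 0, 0)
  expect_equal(propagate(ch, p0, 0L), p0)
  expect_equal(propagate(ch, ch$pi, 17L), ch$pi, tolerance = 1e-12)
  # oracle: literal repeated multiplication
  p <- p0
  for (i in 1:7) p <- as.vector(p %*% ch$P)
  expect_equal(propagate(ch, p0, 7L), p, tolerance = 1e-14)
  tri <- node_chain(triangle_net(c(a = 1L, b = 0L, c = 0L)))
  expect_equal(propagate(tri, c(1, 0, 0), 50L), rep(1 / 3, 3L),
               tolerance = 1e-10)
})

test_that("step covariance matches the matrix-power oracle", {
  for (ch in list(table1_chain(spec_ex1()), table1_chain(spec_ex2()),
                  node_chain(triangle_net(c(a = 1L, b = 0L, c = 0L))))) {
    ystar <- ch$y - sum(ch$pi * ch$y)
    expect_equal(step_covariance(ch, 0L), sum(ch$pi * ystar^2),
                 tolerance = 1e-12)
    Pt <- diag(length(ch$y))
    for (lag in 1:5) {
      Pt <- Pt %*% ch$P
      oracle <- sum(ch$pi * ystar * as.vector(Pt %*% ystar))
      expect_equal(step_covariance(ch, lag), oracle, tolerance = 1e-10)
    }
  }
  # constant attribute: zero covariance at every lag
  flat <- state_chain(matrix(c(.6, .4, .4, .6), 2L, 2L), c(1, 1))
  expect_equal(step_covariance(flat, 0L), 0, tolerance = 1e-14)
  expect_equal(step_covariance(flat, 3L), 0, tolerance = 1e-14)
})

test_that("exact walk variance reproduces the worked illustration values", {
  v <- exact_rw_variance(table1_chain(spec_ex1()), 100L)
  expect_equal(round(v$sd, 3), 0.138)
  expect_equal(round(v$design_effect, 2), 7.64)
  v <- exact_rw_variance(table1_collapse(spec_ex1()), 100L)
  expect_equal(round(v$sd, 3), 0.110)
  expect_equal(round(v$design_effect, 2), 4.88)
  v <- exact_rw_variance(table1_chain(spec_ex2()), 100L)
  expect_equal(round(v$sd, 3), 0.219)
  expect_equal(round(v$design_effect, 2), 19.12)
  v <- exact_rw_variance(table1_collapse(spec_ex2()), 100L)
  expect_equal(round(v$sd, 4), 0.0888, tolerance = 1e-12)
  expect_equal(round(v$design_effect, 2), 3.15)
})

test_that("degenerate and memoryless chains behave as documented", {
  # i.i.d. chain (rows equal to pi): design effect exactly 1
  iid <- state_chain(matrix(0.5, 2L, 2L), c(0, 1))
  v <- exact_rw_variance(iid, 50L)
  expect_equal(v$design_effect, 1, tolerance = 1e-12)
  # constant attribute: zero variance, no design effect
  flat <- state_chain(matrix(c(.6, .4, .4, .6), 2L, 2L), c(1, 1))
  expect_equal(exact_rw_variance(flat, 50L)$variance, 0)
  expect_true(is.na(exact_rw_variance(flat, 50L)$design_effect))
  # four-state exceeds its dyadic collapse at every sample size
  for (s in c(2L, 10L, 100L)) {
    expect_gt(exact_rw_variance(table1_chain(spec_ex1()), s)$variance,
              exact_rw_variance(table1_collapse(spec_ex1()), s)$variance)
  }
})

test_that("chains serialize to CSV and back", {
  ch <- table1_chain(spec_ex1())
  mp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".csv")
  write_chain(ch, mp, sp)
  back <- read_chain(mp, sp)
  expect_equal(back$P, ch$P, tolerance = 1e-12)
  expect_equal(back$pi, ch$pi, tolerance = 1e-12)
  expect_equal(back$y, ch$y)
  expect_equal(back$lambdas, ch$lambdas, tolerance = 1e-10)
})
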