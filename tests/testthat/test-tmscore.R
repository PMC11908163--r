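test_that("kabsch recovers exact rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  s <- kabsch(P, P)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  # 90-degree rotation about z
  P3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Q3 <- P3 %*% t(Rz)
  s3 <- kabsch(P3, Q3)
  expect_equal(s3$rmsd, 0, tolerance = 1e-10)
  expect_equal(s3$rotation, Rz, tolerance = 1e-8)
})

test_that("kabsch rotation is orthonormal with determinant +1, reflections excluded", {
  set.seed(2)
  for (i in 1:20) {
    P <- matrix(rnorm(24), 8, 3)
    Q <- matrix(rnorm(24), 8, 3)
    s <- kabsch(P, Q)
    expect_lt(max(abs(crossprod(s$rotation) - diag(3))), 1e-8)
    expect_equal(det(s$rotation), 1, tolerance = 1e-8)
  }
  # a mirrored point set must not be matched by a reflection
  P <- matrix(rnorm(24), 8, 3)
  Qm <- P; Qm[, 1] <- -Qm[, 1]
  sm <- kabsch(P, Qm)
  expect_equal(det(sm$rotation), 1, tolerance = 1e-8)
  expect_gt(sm$rmsd, 0.1)
})

test_that("kabsch matches the quaternion search oracle on random instances", {
  set.seed(3)
  for (i in 1:25) {
    P <- matrix(rnorm(24), 8, 3)
    Q <- sweep(P %*% t(random_rotation()), 2, rnorm(3), "+") +
      matrix(rnorm(24, 0, 0.3), 8, 3)
    expect_lt(abs(kabsch(P, Q)$rmsd - rmsd_quaternion_oracle(P, Q)), 1e-4)
  }
})

test_that("weighted kabsch down-weights outliers", {
  set.seed(4)
  P <- matrix(rnorm(30), 10, 3)
  Q <- P
  Q[1, ] <- Q[1, ] + 10       # one gross outlier
  w <- c(0, rep(1, 9))
  expect_lt(kabsch(P, Q, weights = w)$rmsd, 1e-10)
  expect_gt(kabsch(P, Q)$rmsd, 1)
  expect_error(kabsch(P[1:2, ], Q[1:2, ]), class = "structembed_degenerate_input_error")
})

test_that("d0 normalization follows the standard closed form", {
  expect_equal(d0_norm(150), 1.24 * 135^(1/3) - 1.8, tolerance = 1e-12)
  expect_equal(d0_norm(15), 0.5)   # floored
  expect_equal(d0_norm(1), 0.5)
  d0s <- d0_norm(15:1000)
  expect_true(all(diff(d0s) >= 0))
  expect_true(all(d0s > 0))
})

test_that("TM-score is 1 for self and rigid copies, and rigid-motion invariant", {
  ch <- make_scaffold("helix", 40L, seed = 6L)
  corr <- cbind(1:40, 1:40)
  expect_equal(tm_score_aligned(ch, ch, corr), 1, tolerance = 1e-9)
  set.seed(7)
  for (i in 1:5) {
    moved <- rigid_copy(ch)
    expect_equal(tm_score_aligned(ch, moved, corr), 1, tolerance = 1e-6)
  }
  # invariance: transforming both chains leaves any pair score unchanged
  p <- perturb_chain(ch, 1.5, seed = 8L)
  base <- tm_score_aligned(ch, p, corr)
  for (i in 1:5) {
    expect_equal(tm_score_aligned(rigid_copy(ch), p, corr), base, tolerance = 1e-6)
    expect_equal(tm_score_aligned(ch, rigid_copy(p), corr), base, tolerance = 1e-6)
  }
  expect_lte(base, 1)
})

test_that("TM-score refinement matches the multi-start superposition oracle", {
  set.seed(9)
  ch <- make_scaffold("helix", 60L, seed = 10L)
  corr <- cbind(1:60, 1:60)
  for (sigma in c(1.0, 2.0)) {
    p <- perturb_chain(ch, sigma, seed = 11L + sigma * 10)
    impl <- tm_score_aligned(ch, p, corr)
    oracle <- tm_multistart_oracle(ch$ca_coords, p$ca_coords,
                                   d0_norm(60), 60, n_starts = 50)
    expect_lt(abs(impl - oracle), 1e-3)
  }
})

test_that("pair-max TM uses both normalizations and is symmetric", {
  a <- make_scaffold("helix", 40L, seed = 12L)
  r <- tm_score_pair_max(a, a)
  expect_equal(r$tm_query, 1, tolerance = 1e-9)
  expect_equal(r$tm_target, 1, tolerance = 1e-9)
  expect_equal(r$tm_max, 1, tolerance = 1e-9)
  b <- perturb_chain(make_scaffold("coil", 52L, seed = 13L), 0.3, seed = 1L)
  r_ab <- tm_score_pair_max(a, b)
  r_ba <- tm_score_pair_max(b, a)
  expect_equal(r_ab$tm_max, r_ba$tm_max, tolerance = 1e-9)
  expect_equal(r_ab$tm_max, max(r_ab$tm_query, r_ab$tm_target), tolerance = 1e-12)
  # shorter chain normalization always gives the larger score here
  expect_gte(r_ab$tm_max + 1e-12, r_ab$tm_query)
})

test_that("unrelated equal-length scaffolds score below the same-fold threshold", {
  h <- make_scaffold("helix", 80L, seed = 14L)
  s <- make_scaffold("strand", 80L, seed = 15L)
  expect_lt(tm_score_pair_max(h, s)$tm_max, 0.5)
})

test_that("TM discretization maps [0,1] onto exactly the 11 first-decimal values", {
  expect_equal(discretize_tm(0.84), 0.8)
  expect_equal(discretize_tm(0.85), 0.9)   # round-half-up
  grid <- seq(0, 1, by = 0.001)
  vals <- sort(unique(discretize_tm(grid)))
  expect_length(vals, 11L)
  expect_equal(vals, seq(0, 1, by = 0.1))
  expect_error(discretize_tm(1.2), class = "structembed_domain_error")
  expect_error(discretize_tm(-0.1), class = "structembed_domain_error")
})

test_that("empty or invalid correspondences raise alignment errors", {
  ch <- make_scaffold("helix", 10L, seed = 1L)
  expect_error(tm_score_aligned(ch, ch, matrix(0L, 0, 2)),
               class = "structembed_alignment_error")
  expect_error(tm_score_aligned(ch, ch, cbind(1, 99)),
               class = "structembed_alignment_error")
})
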