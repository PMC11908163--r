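test_that("scaffold adjacent CA-CA distances match the closed forms", {
  h <- make_scaffold("helix", 30L, seed = 1L)
  dh <- sqrt(rowSums(diff(h$ca_coords)^2))
  expect_equal(dh, rep(sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2), 29),
               tolerance = 1e-10)
  s <- make_scaffold("strand", 30L, seed = 1L)
  dstr <- sqrt(rowSums(diff(s$ca_coords)^2))
  expect_equal(dstr, rep(sqrt(3.3^2 + 1.9^2), 29), tolerance = 1e-10)
})

test_that("all scaffold kinds give adjacent CA distances in the 3.2-4.0 A band", {
  for (kind in c("helix", "strand", "coil")) {
    for (seed in 1:3) {
      ch <- make_scaffold(kind, 40L, seed = seed)
      d <- sqrt(rowSums(diff(ch$ca_coords)^2))
      expect_true(all(d >= 3.2 & d <= 4.0), info = paste(kind, seed))
    }
  }
})

test_that("coils are self-avoiding and reproducible from the seed", {
  c1 <- make_scaffold("coil", 50L, seed = 9L)
  c2 <- make_scaffold("coil", 50L, seed = 9L)
  expect_identical(c1$ca_coords, c2$ca_coords)
  expect_identical(c1$sequence, c2$sequence)
  D <- as.matrix(dist(c1$ca_coords))
  nonadj <- abs(row(D) - col(D)) > 1
  expect_true(all(D[nonadj] >= 4.0 - 1e-9))
})

test_that("zero-sigma perturbation is the identity and seeds differentiate", {
  ch <- make_scaffold("helix", 25L, seed = 2L)
  expect_identical(perturb_chain(ch, 0, seed = 1L)$ca_coords, ch$ca_coords)
  p1 <- perturb_chain(ch, 1.0, seed = 1L)
  p2 <- perturb_chain(ch, 1.0, seed = 2L)
  expect_gt(max(abs(p1$ca_coords - p2$ca_coords)), 0)
  expect_identical(p1$sequence, ch$sequence)
})

test_that("TM-score to the parent decays with perturbation sigma", {
  ch <- make_scaffold("helix", 60L, seed = 3L)
  sigmas <- c(0.5, 3.0)
  tms <- sapply(sigmas, function(s)
    sapply(1:20, function(seed)
      tm_score_pair_max(ch, perturb_chain(ch, s, seed = seed))$tm_max))
  expect_true(all(tms[, 1] < 1))
  expect_gt(mean(tms[, 1]), mean(tms[, 2]))
  # non-increasing expected TM over a finer sigma ladder
  ladder <- c(0.25, 0.75, 1.5, 3.0)
  means <- sapply(ladder, function(s)
    mean(sapply(1:20, function(seed)
      tm_score_pair_max(ch, perturb_chain(ch, s, seed = seed))$tm_max)))
  expect_true(all(diff(means) <= 0))
})

test_that("family datasets have the declared shape and symmetric TM ground truth", {
  spec <- synthetic_spec(n_families = 2L, members_per_family = 3L,
                         length_range = c(30L, 36L),
                         perturbation_sigmas = c(0, 0.5, 1), seed = 21L)
  ds <- make_family_dataset(spec)
  expect_length(ds$chains, 6L)
  expect_equal(sort(unique(ds$families)), c("F01", "F02"))
  expect_equal(dim(ds$tm), c(6L, 6L))
  expect_equal(ds$tm, t(ds$tm))
  expect_equal(unname(diag(ds$tm)), rep(1, 6))
  # reproducibility
  ds2 <- make_family_dataset(spec)
  expect_identical(ds$tm, ds2$tm)
  expect_identical(ds$families, ds2$families)
  # within-family pairs are more similar than between-family pairs
  ut <- upper.tri(ds$tm)
  same <- outer(ds$families, ds$families, "==")
  expect_gt(mean(ds$tm[ut & same]), mean(ds$tm[ut & !same]))
  # all chains satisfy the chain invariants (constructor enforces them)
  for (ch in ds$chains) expect_s3_class(ch, "protein_chain")
})

test_that("symmetric assemblies are exact cyclic copies with distinct chain ids", {
  ch <- make_scaffold("strand", 20L, seed = 4L)
  asm <- make_symmetric_assembly(ch, 2L, radius = 12)
  expect_length(asm$chains, 2L)
  # copy B equals copy A rotated by 180 degrees about z
  ang <- pi
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  a <- asm$chains[["A"]]$ca_coords
  b <- asm$chains[["B"]]$ca_coords
  # direct reconstruction: rotate centred chain, translate radially
  centred <- sweep(ch$ca_coords, 2, colMeans(ch$ca_coords))
  b_direct <- sweep(centred %*% t(R), 2, 12 * c(cos(ang), sin(ang), 0), "+")
  expect_equal(b, b_direct, tolerance = 1e-12)
  expect_lt(max(abs(sweep((sweep(b, 2, 12 * c(cos(ang), sin(ang), 0))) %*% R, 2,
                          12 * c(1, 0, 0), "+") - a)), 1e-9)
  asm24 <- make_symmetric_assembly(ch, 24L)
  expect_length(asm24$chains, 24L)
  expect_identical(make_symmetric_assembly(ch, 5L)$chains[["C"]]$ca_coords,
                   make_symmetric_assembly(ch, 5L)$chains[["C"]]$ca_coords)
  expect_error(make_symmetric_assembly(ch, 25L), class = "structembed_validation_error")
  expect_error(make_symmetric_assembly(ch, 1L), class = "structembed_validation_error")
})

test_that("invalid dataset specs are rejected", {
  expect_error(synthetic_spec(scaffold_mix = c(h = 0.5, s = 0.2, c = 0.2)),
               class = "structembed_validation_error")
  expect_error(synthetic_spec(perturbation_sigmas = c(-1)),
               class = "structembed_validation_error")
  expect_error(synthetic_spec(n_families = 0L),
               class = "structembed_validation_error")
})
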