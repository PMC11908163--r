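ns <- asNamespace("structembed")

mk_tm <- function(ids, vals) {
  n <- length(ids)
  tm <- matrix(0, n, n, dimnames = list(ids, ids))
  tm[upper.tri(tm)] <- vals
  tm <- tm + t(tm); diag(tm) <- 1
  tm
}

test_that("pair datasets enumerate unordered pairs with discretized targets", {
  ids <- c("a", "b", "c", "d")
  tm <- mk_tm(ids, c(0.84, 0.12, 0.5, 0.31, 0.99, 0.07))
  pairs <- build_pair_dataset(ids, tm)
  expect_equal(nrow(pairs), 6L)                        # 4 choose 2
  expect_false(any(pairs$id_a == pairs$id_b))          # no self-pairs
  expect_true(all(round(pairs$tm_target * 10) %in% 0:10))
  expect_equal(pairs$tm_target, round(pairs$tm_target * 10) / 10, tolerance = 1e-12)
  expect_equal(pairs$tm_target[pairs$id_a == "a" & pairs$id_b == "b"], 0.8)
  tm_bad <- tm; tm_bad[1, 2] <- NA; tm_bad[2, 1] <- NA
  expect_error(build_pair_dataset(ids, tm_bad), class = "structembed_data_error")
})

test_that("balanced sampling is uniform over the non-empty TM bins", {
  # all 11 bins populated with very different counts
  targets <- rep(seq(0, 1, 0.1), times = c(500, 200, 100, 50, 20, 10, 5, 5, 5, 5, 100))
  pairs <- data.frame(id_a = "x", id_b = "y", tm_target = targets)
  set.seed(1)
  draws <- unlist(lapply(1:100, function(i) sample_balanced_batch(pairs, 100L)))
  counts <- table(factor(pairs$tm_target[draws], levels = seq(0, 1, 0.1)))
  # chi-square uniformity over the 11 bins
  p <- chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 0.01)
  # each bin frequency within 3 standard errors of 1/11
  n <- length(draws)
  se <- sqrt((1 / 11) * (10 / 11) / n)
  expect_true(all(abs(as.numeric(counts) / n - 1 / 11) < 3 * se + 1e-12))
})

test_that("balanced sampling restricts to non-empty bins and is reproducible", {
  pairs <- data.frame(id_a = "x", id_b = "y",
                      tm_target = rep(c(0, 1), times = c(30, 10)))
  set.seed(2)
  b <- sample_balanced_batch(pairs, 2000L)
  drawn <- pairs$tm_target[b]
  expect_setequal(unique(drawn), c(0, 1))
  expect_equal(mean(drawn == 0), 0.5, tolerance = 0.05)
  set.seed(3); b1 <- sample_balanced_batch(pairs, 50L)
  set.seed(3); b2 <- sample_balanced_batch(pairs, 50L)
  expect_identical(b1, b2)
  expect_error(sample_balanced_batch(pairs[0, ], 4L), class = "structembed_data_error")
})

test_that("twin loss follows its closed forms and is symmetric", {
  expect_equal(twin_loss(c(1, 0), c(1, 0) * 0.8, targets = 1), 0)
  expect_equal(twin_loss(rbind(c(1, 0)), rbind(c(1, 1) / sqrt(2)), targets = 0.8),
               (sqrt(2) / 2 - 0.8)^2, tolerance = 1e-12)
  # batch mean of squared errors 0.01 and 0.04
  a <- rbind(c(1, 0), c(1, 0))
  b <- rbind(c(1, 0), c(1, 0))
  t1 <- c(1 - 0.1, 1 - 0.2)
  expect_equal(twin_loss(a, b, t1), mean(c(0.01, 0.04)), tolerance = 1e-12)
  set.seed(4)
  ea <- matrix(rnorm(12), 3); eb <- matrix(rnorm(12), 3); tt <- runif(3)
  expect_identical(twin_loss(ea, eb, tt), twin_loss(eb, ea, tt))
})

test_that("AUPRC matches closed forms and a permutation null", {
  # perfect ordering
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # constant scores: single operating point, precision = prevalence
  expect_equal(auprc(rep(0.5, 10), c(rep(1, 2), rep(0, 8))), 0.2)
  # random scores concentrate near prevalence
  set.seed(5)
  n <- 1000; prev <- 0.2
  labs <- rep(c(TRUE, FALSE), times = c(n * prev, n * (1 - prev)))
  ap <- replicate(50, auprc(runif(n), labs))
  null_sd <- sd(ap)
  expect_lt(abs(mean(ap) - prev), 3 * null_sd / sqrt(50) + 0.01)
  expect_error(auprc(runif(5), rep(TRUE, 5)), class = "structembed_metric_error")
})

test_that("grouped splits partition groups, never ids across folds", {
  ids <- sprintf("d%02d", 1:40)
  groups <- rep(sprintf("F%02d", 1:10), each = 4)
  folds <- grouped_split(ids, groups, k = 10L, seed = 1L)
  expect_length(folds, 10L)
  expect_setequal(unlist(folds), ids)
  # one family per fold here
  for (f in folds) expect_length(unique(groups[match(f, ids)]), 1L)
  # no family straddles folds for k = 3 either
  folds3 <- grouped_split(ids, groups, k = 3L, seed = 2L)
  fam_fold <- lapply(folds3, function(f) unique(groups[match(f, ids)]))
  expect_equal(sum(lengths(fam_fold)), 10L)
  expect_false(any(duplicated(unlist(fam_fold))))
  expect_identical(grouped_split(ids, groups, 5L, seed = 3L),
                   grouped_split(ids, groups, 5L, seed = 3L))
  expect_error(grouped_split(ids, groups, k = 11L), class = "structembed_split_error")
})

test_that("the learning-rate schedule warms up linearly then decays to zero", {
  lrs <- vapply(1:100, function(s) ns$lr_schedule(s, 100, 20, 1e-3), 0)
  expect_equal(lrs[1:20], 1e-3 * (1:20) / 20, tolerance = 1e-12)
  expect_equal(lrs[100], 0, tolerance = 1e-9)
  expect_true(all(diff(lrs[20:100]) <= 1e-12))
  expect_equal(ns$lr_schedule(60, 100, 20, 1e-3), 1e-3 * 0.5, tolerance = 1e-12)
})

test_that("desk training reduces the loss, is reproducible, and checkpoints the AUPRC max", {
  tf <- desk_fit_for_tests()
  fit <- tf$fit
  h <- fit$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_equal(fit$best_epoch, max(which(h$auprc == max(h$auprc))))
  expect_equal(fit$best_auprc, max(h$auprc))
  expect_true(all(is.finite(h$loss)))
  # determinism: an identical short run gives an identical history
  fit2 <- structembed_fit(tf$ds$chains, tf$ds$tm,
                          agg_config = desk_aggregator_config(seed = 3L),
                          config = train_config(epochs = 6L, pairs_per_epoch = 64L,
                                                validation_fraction = 0.1, seed = 4L))
  expect_identical(fit2$history, h)
  expect_identical(unlist(fit2$model$params), unlist(fit$model$params))
})

test_that("fitted models expose working methods", {
  tf <- desk_fit_for_tests()
  fit <- tf$fit
  expect_output(print(fit), "twin-network")
  expect_output(print(summary(fit)), "Spearman")
  embs <- predict(fit, tf$ds$chains)
  expect_equal(dim(embs), c(length(tf$ds$chains), 64L))
  expect_identical(rownames(embs), names(tf$ds$chains))
  r <- residuals(fit)
  expect_length(r, nrow(fit$train_pairs))
  sims <- predict(fit, fit$val_pairs[, c("id_a", "id_b")], type = "similarity")
  expect_true(all(sims >= -1 - 1e-9 & sims <= 1 + 1e-9))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("group-level validation splits keep whole families out of training pairs", {
  tf <- desk_fit_for_tests()
  fit <- structembed_fit(tf$ds$chains, tf$ds$tm,
                         agg_config = desk_aggregator_config(seed = 3L),
                         config = train_config(epochs = 3L, pairs_per_epoch = 32L,
                                               validation_fraction = 0.4,
                                               validation_by = "group", seed = 6L),
                         groups = tf$ds$families)
  val_fams <- unique(c(tf$ds$families[fit$val_pairs$id_a],
                       tf$ds$families[fit$val_pairs$id_b]))
  held <- setdiff(val_fams, unique(c(tf$ds$families[fit$train_pairs$id_a],
                                     tf$ds$families[fit$train_pairs$id_b])))
  expect_gte(length(held), 1L)
})
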