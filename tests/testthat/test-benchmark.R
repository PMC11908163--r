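toy_classification <- function() {
  data.frame(
    id = c("d1", "d2", "d3", "d4", "d5"),
    family      = c("f1", "f1", "f2", "f3", "f4"),
    superfamily = c("sf1", "sf1", "sf1", "sf2", "sf3"),
    fold        = c("c1", "c1", "c1", "c1", "c2"),
    stringsAsFactors = FALSE
  )
}

test_that("hierarchy labelling follows the tri-state benchmark definitions", {
  cls <- toy_classification()
  fam <- label_pairs_hierarchy(cls, "family")
  expect_equal(fam$labels["d1", "d2"], "TP")       # same family
  expect_equal(fam$labels["d1", "d3"], "IGNORE")   # same superfamily, diff family
  expect_equal(fam$labels["d1", "d5"], "FP")       # different fold
  sup <- label_pairs_hierarchy(cls, "superfamily")
  expect_equal(sup$labels["d1", "d3"], "TP")       # same sf, different family
  expect_equal(sup$labels["d1", "d2"], "IGNORE")   # same family is excluded
  expect_equal(sup$labels["d1", "d4"], "IGNORE")   # same fold, different sf
  expect_equal(sup$labels["d2", "d5"], "FP")
  fld <- label_pairs_hierarchy(cls, "fold")
  expect_equal(fld$labels["d1", "d4"], "TP")       # same fold, different sf
  expect_equal(fld$labels["d1", "d3"], "IGNORE")   # same superfamily excluded
  expect_equal(fld$labels["d4", "d5"], "FP")
  # self-pairs always IGNORE; labelling is a partition
  for (lv in c("family", "superfamily", "fold")) {
    lab <- label_pairs_hierarchy(cls, lv)$labels
    expect_true(all(diag(lab) == "IGNORE"))
    expect_true(all(lab %in% c("TP", "FP", "IGNORE")))
  }
  cls$fold[2] <- NA
  expect_error(label_pairs_hierarchy(cls, "family"), class = "structembed_data_error")
})

test_that("TM labelling applies the 0.8/0.5 thresholds with an IGNORE band", {
  ids <- c("p", "q", "r", "s")
  tm <- matrix(1, 4, 4, dimnames = list(ids, ids))
  tm["p", "q"] <- tm["q", "p"] <- 0.81
  tm["p", "r"] <- tm["r", "p"] <- 0.65
  tm["p", "s"] <- tm["s", "p"] <- 0.49
  tm["q", "r"] <- tm["r", "q"] <- 0.80   # exactly at the TP threshold
  tm["q", "s"] <- tm["s", "q"] <- 0.50   # exactly at the FP threshold
  tm["r", "s"] <- tm["s", "r"] <- 0.2
  lab <- label_pairs_tm(tm)
  expect_equal(lab$labels["p", "q"], "TP")
  expect_equal(lab$labels["p", "r"], "IGNORE")
  expect_equal(lab$labels["p", "s"], "FP")
  expect_equal(lab$labels["q", "r"], "IGNORE")   # strictly greater than 0.8
  expect_equal(lab$labels["q", "s"], "IGNORE")   # strictly below 0.5
  expect_true(all(diag(lab$labels) == "IGNORE"))
  expect_error(label_pairs_tm(tm, tp_thresh = 0.4, fp_thresh = 0.5),
               class = "structembed_validation_error")
})

test_that("sensitivity to the first FP matches its definition and a recount oracle", {
  expect_equal(sensitivity_to_first_fp(c("TP", "TP", "FP", "TP")), 2 / 3)
  expect_equal(sensitivity_to_first_fp(c("FP", "TP", "TP")), 0)
  expect_equal(sensitivity_to_first_fp(c("TP", "TP", "TP")), 1)
  # IGNORE neither counts nor terminates
  expect_equal(sensitivity_to_first_fp(c("TP", "IGNORE", "TP", "IGNORE", "FP", "TP")), 2 / 3)
  # no FP in the ranking: fraction of TPs present
  expect_equal(sensitivity_to_first_fp(c("TP", "IGNORE"), total_tp = 2), 0.5)
  expect_error(sensitivity_to_first_fp(c("FP", "IGNORE")),
               class = "structembed_undefined_error")
  set.seed(1)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    labs <- sample(c("TP", "FP", "IGNORE"), n, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
    if (sum(labs == "TP") == 0) labs[1] <- "TP"
    expect_equal(sensitivity_to_first_fp(labs),
                 sensitivity_recount(labs, sum(labs == "TP")))
  }
})

test_that("all-vs-all retrieval handles separable and anti-correlated embeddings", {
  fams <- rep(c("f1", "f2", "f3"), each = 4)
  ids <- sprintf("m%02d", 1:12)
  cls <- data.frame(id = ids, family = fams, superfamily = fams, fold = fams)
  labs <- label_pairs_hierarchy(cls, "family")
  onehot <- diag(3)[match(fams, c("f1", "f2", "f3")), ]
  rownames(onehot) <- ids
  res <- run_all_vs_all(onehot + 1e-9, labs)
  expect_true(all(res$per_query$sensitivity == 1))
  expect_equal(res$fraction_perfect, 1)
  # scores anti-correlated with membership: every same-family pair is opposed
  # (cosine -1) while cross-family pairs are orthogonal, so the first hit is
  # always an FP
  ids2 <- c("a1", "a2", "b1", "b2")
  fams2 <- c("fa", "fa", "fb", "fb")
  cls2 <- data.frame(id = ids2, family = fams2, superfamily = fams2, fold = fams2)
  anti <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  rownames(anti) <- ids2
  res2 <- run_all_vs_all(anti, label_pairs_hierarchy(cls2, "family"),
                         tie_policy = "pessimistic")
  expect_true(all(res2$per_query$sensitivity == 0))
})

test_that("all-vs-all matches a brute-force per-query recomputation", {
  set.seed(2)
  n <- 50
  fams <- sample(sprintf("f%d", 1:6), n, replace = TRUE)
  while (any(table(fams) < 2)) fams <- sample(sprintf("f%d", 1:6), n, replace = TRUE)
  ids <- sprintf("x%02d", 1:n)
  cls <- data.frame(id = ids, family = fams, superfamily = fams, fold = fams)
  labs <- label_pairs_hierarchy(cls, "family")
  E <- matrix(rnorm(n * 8), n, 8, dimnames = list(ids, NULL))
  res <- run_all_vs_all(E, labs, tie_policy = "stable")
  U <- E / sqrt(rowSums(E^2))
  S <- tcrossprod(U)
  for (qid in res$per_query$id) {
    others <- setdiff(ids, qid)
    lab <- labs$labels[qid, others]
    ord <- order(-S[qid, others])
    expect_equal(res$per_query$sensitivity[res$per_query$id == qid],
                 sensitivity_recount(lab[ord], sum(lab == "TP")))
  }
})

test_that("pessimistic tie handling lower-bounds every other tie order", {
  # two TPs, one FP, one IGNORE all at the same score
  ids <- c("q", "a", "b", "c", "d")
  fams <- c("f1", "f1", "f1", "f2", "f3")
  cls <- data.frame(id = ids, family = fams, superfamily = fams, fold = fams)
  labs <- label_pairs_hierarchy(cls, "family")
  E <- rbind(c(1, 0), c(1, 1), c(1, 1), c(1, 1), c(-1, 0))
  rownames(E) <- ids
  sens <- function(pol) {
    r <- run_all_vs_all(E, labs, tie_policy = pol)
    r$per_query$sensitivity[r$per_query$id == "q"]
  }
  # a, b, c are tied for query q; pessimistic puts the FP (c) first
  expect_equal(sens("pessimistic"), 0)
  expect_equal(sens("optimistic"), 1)
  expect_gte(sens("stable"), sens("pessimistic"))
  expect_lte(sens("stable"), sens("optimistic"))
})

test_that("queries without true positives are excluded and counted", {
  ids <- c("q1", "q2", "lonely")
  fams <- c("f1", "f1", "f9")
  cls <- data.frame(id = ids, family = fams, superfamily = fams, fold = fams)
  labs <- label_pairs_hierarchy(cls, "family")
  E <- matrix(rnorm(9), 3, dimnames = list(ids, NULL))
  res <- run_all_vs_all(E, labs)
  expect_equal(res$n_queries, 2L)
  expect_equal(res$n_excluded, 1L)
})

test_that("correlation report returns 1 for perfect predictions and a null band otherwise", {
  set.seed(3)
  tm <- runif(1000)
  rep1 <- correlation_report(tm, tm, n_resamples = 5)
  expect_equal(rep1$pearson_all, 1, tolerance = 1e-12)
  expect_true(all(abs(rep1$pearson_resampled - 1) < 1e-12))
  # independent predictions: |r| small, inside a permutation null band
  pred <- rnorm(1000)
  rep2 <- correlation_report(pred, tm, n_resamples = 5)
  null_r <- replicate(200, cor(sample(pred), tm))
  expect_lt(abs(rep2$pearson_all), 3 * sd(null_r) + 0.02)
})

test_that("uniform resampling recovers correlation hidden by a skewed TM distribution", {
  # mimic an all-vs-all TM distribution: 95% of mass at low TM plus noise
  set.seed(4)
  n <- 4000
  tm <- c(runif(n * 0.95, 0, 0.25), runif(n * 0.05, 0.25, 1))
  pred <- tm + rnorm(length(tm), 0, 0.08)
  rep3 <- correlation_report(pred, tm, n_resamples = 20, sample_size = 300)
  expect_gt(mean(rep3$pearson_resampled, na.rm = TRUE), rep3$pearson_all)
  expect_error(correlation_report(rep(1, 10), runif(10)),
               class = "structembed_metric_error")
})
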