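#' Tri-state pair labels from a classification hierarchy
#'
#' Labels every ordered pair of distinct items TP, FP or IGNORE under the
#' standard fold-benchmark convention. At each level, FP is always
#' "different fold"; TP is, respectively: same family (family level), same
#' superfamily but different family (superfamily level), same fold but
#' different superfamily (fold level). All remaining pairs — including
#' self-pairs — are IGNORE: they neither count as hits nor terminate the
#' ranking scan.
#'
#' @param classification data.frame with columns `id`, `family`,
#'   `superfamily`, `fold`, one row per item.
#' @param level `"family"`, `"superfamily"`, or `"fold"`.
#' @return An object of class `pair_labels`: list with `ids` and an N x N
#'   character `labels` matrix.
#' @export
label_pairs_hierarchy <- function(classification, level = c("family", "superfamily", "fold")) {
  level <- match.arg(level)
  req <- c("id", "family", "superfamily", "fold")
  if (!all(req %in% names(classification)))
    se_stop("data_error", "classification needs columns %s", paste(req, collapse = ", "))
  if (anyNA(classification[req]))
    se_stop("data_error", "unclassified id(s) present")
  ids <- as.character(classification$id)
  same <- function(col) outer(classification[[col]], classification[[col]], "==")
  sf <- same("family"); ss <- same("superfamily"); sd <- same("fold")
  tp <- switch(level,
               family = sf,
               superfamily = ss & !sf,
               fold = sd & !ss)
  lab <- matrix("IGNORE", length(ids), length(ids), dimnames = list(ids, ids))
  lab[!sd] <- "FP"
  lab[tp] <- "TP"
  diag(lab) <- "IGNORE"
  structure(list(ids = ids, labels = lab), class = "pair_labels")
}

#' Tri-state pair labels from a TM-score matrix
#'
#' TP if `tm > tp_thresh` (default 0.8), FP if `tm < fp_thresh` (default
#' 0.5), IGNORE otherwise — the thresholds conventionally separating same
#' fold from distinct folds in full-chain benchmarks. Self-pairs are IGNORE.
#'
#' @param tm_matrix symmetric TM-score matrix with id dimnames.
#' @param tp_thresh,fp_thresh thresholds with `fp_thresh < tp_thresh`.
#' @return A `pair_labels` object.
#' @export
label_pairs_tm <- function(tm_matrix, tp_thresh = 0.8, fp_thresh = 0.5) {
  if (fp_thresh >= tp_thresh)
    se_stop("validation_error", "fp_thresh must be < tp_thresh")
  ids <- rownames(tm_matrix)
  if (is.null(ids)) se_stop("data_error", "tm_matrix needs id dimnames")
  lab <- matrix("IGNORE", nrow(tm_matrix), ncol(tm_matrix), dimnames = dimnames(tm_matrix))
  lab[tm_matrix > tp_thresh] <- "TP"
  lab[tm_matrix < fp_thresh] <- "FP"
  diag(lab) <- "IGNORE"
  structure(list(ids = ids, labels = lab), class = "pair_labels")
}

#' Sensitivity up to the first false positive
#'
#' Scans a ranked hit list and returns the fraction of the query's true
#' positives ranked strictly before the first FP. IGNORE hits neither count
#' nor terminate the scan. If no FP appears, the value is the fraction of
#' the query's TPs present in the ranking.
#'
#' @param ranked_labels character vector of labels (`"TP"`, `"FP"`,
#'   `"IGNORE"`) in rank order, self-comparison excluded.
#' @param total_tp total number of TPs for this query in the label set
#'   (defaults to the number of TPs in the ranking).
#' @return Sensitivity in [0, 1].
#' @export
sensitivity_to_first_fp <- function(ranked_labels, total_tp = sum(ranked_labels == "TP")) {
  if (total_tp < 1L)
    se_stop("undefined_error", "sensitivity undefined for a query with no TPs")
  first_fp <- match("FP", ranked_labels)
  upto <- if (is.na(first_fp)) ranked_labels else ranked_labels[seq_len(first_fp - 1L)]
  sum(upto == "TP") / total_tp
}

order_with_ties <- function(scores, labels, tie_policy) {
  tie_rank <- switch(tie_policy,
    stable = seq_along(scores),
    pessimistic = match(labels, c("FP", "IGNORE", "TP")),
    optimistic = match(labels, c("TP", "IGNORE", "FP")),
    se_stop("validation_error", "unknown tie_policy '%s'", tie_policy))
  order(-scores, tie_rank, seq_along(scores))
}

#' All-vs-all retrieval benchmark
#'
#' For every query with at least one TP, ranks all other items by cosine
#' similarity (descending; ties resolved by `tie_policy`) and computes the
#' sensitivity up to the first FP. Queries without any TP are excluded and
#' counted. The descending-sorted sensitivity values form the standard
#' sorted-sensitivity curve.
#'
#' @param embeddings numeric matrix of embeddings, rownames = ids.
#' @param labels a `pair_labels` object covering the same ids.
#' @param tie_policy `"pessimistic"` (equal-score FPs ranked first — a lower
#'   bound; default), `"stable"`, or `"optimistic"`.
#' @return List with `per_query` (data.frame id, sensitivity, n_tp),
#'   `sorted_sensitivity`, `n_queries`, `n_excluded` (no-TP queries), and
#'   `fraction_perfect` (queries at sensitivity 1.0).
#' @export
run_all_vs_all <- function(embeddings, labels,
                           tie_policy = c("pessimistic", "stable", "optimistic")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(labels, "pair_labels"))
  ids <- rownames(embeddings)
  if (is.null(ids) || !all(ids %in% labels$ids))
    se_stop("data_error", "embeddings rownames must be covered by the labels")
  U <- embeddings / sqrt(rowSums(embeddings^2))
  S <- tcrossprod(U)
  res <- lapply(ids, function(qid) {
    others <- setdiff(ids, qid)
    lab <- labels$labels[qid, others]
    n_tp <- sum(lab == "TP")
    if (n_tp == 0L) return(NULL)
    sc <- S[qid, others]
    ord <- order_with_ties(sc, lab, tie_policy)
    data.frame(id = qid,
               sensitivity = sensitivity_to_first_fp(lab[ord], total_tp = n_tp),
               n_tp = n_tp, stringsAsFactors = FALSE)
  })
  excluded <- sum(vapply(res, is.null, TRUE))
  per_query <- do.call(rbind, res)
  if (is.null(per_query))
    se_stop("data_error", "no query has a true positive")
  list(per_query = per_query,
       sorted_sensitivity = sort(per_query$sensitivity, decreasing = TRUE),
       n_queries = nrow(per_query),
       n_excluded = excluded,
       fraction_perfect = mean(per_query$sensitivity == 1))
}

#' Pearson correlation with uniform TM resampling
#'
#' Reports the overall Pearson correlation between predicted scores and true
#' TM-scores, plus correlations on resamples drawn so that the true TM values
#' are uniformly distributed over equal-width bins spanning [0, 1] (bins are
#' drawn uniformly among the non-empty ones, then a value within the bin,
#' with replacement). On heavily skewed TM distributions — where most pairs
#' are unrelated — the resampled correlations are the more faithful measure
#' of how well predictions track similarity across the whole range.
#'
#' @param pred_scores predicted similarity scores.
#' @param true_tm matched TM-scores in [0, 1].
#' @param n_resamples number of uniform resamples (default 10).
#' @param bins number of equal-width bins over [0, 1] (default 10).
#' @param sample_size draws per resample (default `min(n, 200)`).
#' @param seed RNG seed.
#' @return List with `pearson_all` and `pearson_resampled` (length
#'   `n_resamples`).
#' @export
correlation_report <- function(pred_scores, true_tm, n_resamples = 10L, bins = 10L,
                               sample_size = min(length(true_tm), 200L), seed = 1L) {
  n <- length(true_tm)
  if (length(pred_scores) != n || n < 3L)
    se_stop("validation_error", "need matched vectors of length >= 3")
  if (stats::sd(pred_scores) == 0 || stats::sd(true_tm) == 0)
    se_stop("metric_error", "zero variance input")
  bin_of <- pmin(bins, floor(true_tm * bins) + 1L)
  by_bin <- split(seq_len(n), bin_of)
  rs <- with_seed(seed, vapply(seq_len(n_resamples), function(r) {
    bsel <- sample.int(length(by_bin), sample_size, replace = TRUE)
    idx <- vapply(bsel, function(b) {
      rows <- by_bin[[b]]
      rows[sample.int(length(rows), 1L)]
    }, 0L)
    if (stats::sd(true_tm[idx]) == 0) return(NA_real_)
    stats::cor(pred_scores[idx], true_tm[idx])
  }, 0))
  list(pearson_all = stats::cor(pred_scores, true_tm), pearson_resampled = rs)
}
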