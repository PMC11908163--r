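#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (optionally weighted) RMSD of `R p_i + t` onto `q_i`, via SVD of the
#' cross-covariance matrix with the usual determinant correction that
#' excludes reflections.
#'
#' @param P,Q numeric N x 3 coordinate matrices (N >= 3).
#' @param weights optional non-negative N-vector of weights.
#' @return A list of class `superposition` with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` (in the metric of `weights`).
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' s <- kabsch(P, P)
#' s$rmsd  # 0
#' @export
kabsch <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  if (n < 3L || nrow(Q) != n || ncol(P) != 3L || ncol(Q) != 3L)
    se_stop("degenerate_input_error", "kabsch needs matched N x 3 inputs with N >= 3")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    se_stop("degenerate_input_error", "invalid weights")
  w <- w / sum(w)
  pbar <- colSums(P * w); qbar <- colSums(Q * w)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  H <- crossprod(Pc * w, Qc)             # sum_i w_i p_i q_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- qbar - as.numeric(R %*% pbar)
  dev <- Pc %*% t(R) - Qc
  rmsd <- sqrt(sum(w * rowSums(dev^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

apply_superposition <- function(sup, X) {
  sweep(as.matrix(X) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' TM-score distance scale d0(L)
#'
#' The length-dependent normalization `d0(L) = 1.24 (L - 15)^{1/3} - 1.8`
#' Angstrom, floored at 0.5, which makes the TM-score approximately
#' independent of protein size.
#'
#' @param L normalizing chain length (>= 1).
#' @return d0 in Angstrom (> 0).
#' @examples
#' d0_norm(150)  # about 4.561
#' @export
d0_norm <- function(L) {
  if (any(L < 1)) se_stop("validation_error", "L must be >= 1")
  x <- L - 15
  raw <- 1.24 * sign(x) * abs(x)^(1/3) - 1.8
  pmax(0.5, raw)
}

tm_sum <- function(d2, d0, Lnorm) sum(1 / (1 + d2 / d0^2)) / Lnorm

#' TM-score for a fixed residue correspondence
#'
#' Computes the TM-score
#' `TM = (1/L_norm) * sum_i 1 / (1 + (d_i / d0(L_norm))^2)`
#' over the corresponded CA pairs, maximized over rigid superpositions by
#' iterative Kabsch refinement from several deterministic fragment seeds
#' (all pairs, halves, quarters): each seed is refined by re-superposing on
#' the close-pair subset under a cutoff shrinking from max(d0, 4.5) A to d0,
#' and the best score over all visited superpositions is returned.
#' `L_norm` is the full length of the normalizing chain, not the number of
#' corresponded pairs, so the score is in (0, 1] and penalizes unmatched
#' residues.
#'
#' @param query,target [protein_chain] objects.
#' @param correspondence integer matrix with two columns (query index,
#'   target index), at least one row.
#' @param normalize_by `"query"` or `"target"`: whose length sets `L_norm`.
#' @return TM-score in (0, 1]; invariant to rigid motions of either chain.
#' @export
tm_score_aligned <- function(query, target, correspondence,
                             normalize_by = c("query", "target")) {
  normalize_by <- match.arg(normalize_by)
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) < 1L)
    se_stop("alignment_error", "empty correspondence")
  Lq <- chain_length(query); Lt <- chain_length(target)
  if (any(correspondence[, 1] < 1 | correspondence[, 1] > Lq) ||
      any(correspondence[, 2] < 1 | correspondence[, 2] > Lt))
    se_stop("alignment_error", "correspondence indices out of range")
  P <- query$ca_coords[correspondence[, 1], , drop = FALSE]
  Q <- target$ca_coords[correspondence[, 2], , drop = FALSE]
  Lnorm <- if (normalize_by == "query") Lq else Lt
  d0 <- d0_norm(Lnorm)
  n <- nrow(P)
  if (n < 3L) {
    # too few pairs for a meaningful superposition: superpose exactly by
    # translation (and, for 2 points, rotation aligning the segment)
    if (n == 1L) return(tm_sum(0, d0, Lnorm))
    v1 <- P[2, ] - P[1, ]; v2 <- Q[2, ] - Q[1, ]
    # after optimal rigid motion the two segments share midpoint & direction
    d <- abs(sqrt(sum(v1^2)) - sqrt(sum(v2^2))) / 2
    return(tm_sum(rep(d^2, 2), d0, Lnorm))
  }
  tm_refine_cpp(P, Q, d0, Lnorm, 20L)
}

#' Maximum TM-score over both normalizations
#'
#' For equal-length chains the correspondence is the identity; for unequal
#' lengths the shorter chain is slid along the longer one and the contiguous
#' offset maximizing `tm_max` is kept (a deliberate simplification of full
#' structure alignment; externally computed correspondences can be supplied
#' to [tm_score_aligned] instead). Returns the query- and target-normalized
#' scores and their maximum, the convention used to build training targets.
#'
#' @param a,b [protein_chain] objects (query, target).
#' @return A list of class `tm_result` with `tm_query`, `tm_target`,
#'   `tm_max`, and the `correspondence` used.
#' @export
tm_score_pair_max <- function(a, b) {
  La <- chain_length(a); Lb <- chain_length(b)
  offsets <- 0:abs(La - Lb)
  Ls <- min(La, Lb)
  best <- NULL
  for (off in offsets) {
    corr <- if (La <= Lb) cbind(seq_len(Ls), seq_len(Ls) + off)
            else cbind(seq_len(Ls) + off, seq_len(Ls))
    tq <- tm_score_aligned(a, b, corr, normalize_by = "query")
    tt <- tm_score_aligned(a, b, corr, normalize_by = "target")
    if (is.null(best) || max(tq, tt) > best$tm_max)
      best <- list(tm_query = tq, tm_target = tt, tm_max = max(tq, tt),
                   correspondence = corr)
  }
  structure(best, class = "tm_result")
}

#' Discretize a TM-score to the nearest first-decimal value
#'
#' Rounds to one decimal place with the round-half-up convention, mapping
#' [0, 1] onto the 11 values {0.0, 0.1, ..., 1.0} used as regression targets.
#'
#' @param t TM-score(s) in [0, 1].
#' @return Value(s) in {0.0, 0.1, ..., 1.0}.
#' @examples
#' discretize_tm(0.84)  # 0.8
#' discretize_tm(0.85)  # 0.9
#' @export
discretize_tm <- function(t) {
  if (any(t < 0 | t > 1)) se_stop("domain_error", "TM-score must lie in [0, 1]")
  # small epsilon keeps the half-up convention stable against binary
  # representation of decimals like 0.15
  pmin(1, floor(t * 10 + 0.5 + 1e-9) / 10)
}
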