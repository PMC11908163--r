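# Independent oracles used across the suite. These deliberately avoid the
# package's own superposition/refinement code paths.

random_quaternion <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)  # column-major: columns are images of the basis vectors
}

random_rotation <- function() quat_to_rotmat(random_quaternion())

# RMSD of P onto Q for a given rotation, with the optimal translation
# (centroid alignment) applied in closed form.
rmsd_given_rotation <- function(P, Q, R, w = NULL) {
  n <- nrow(P)
  if (is.null(w)) w <- rep(1 / n, n) else w <- w / sum(w)
  PR <- P %*% t(R)
  t_opt <- colSums(Q * w) - colSums(PR * w)
  dev <- sweep(PR, 2, -t_opt) - Q
  sqrt(sum(w * rowSums(dev^2)))
}

# Quaternion search oracle for the optimal-superposition RMSD: coarse random
# sampling of SO(3), then Nelder-Mead polish of the best candidates in
# quaternion space. Independent of any SVD-based code.
rmsd_quaternion_oracle <- function(P, Q, n_grid = 2000, n_polish = 3) {
  objective <- function(q) {
    nq <- sqrt(sum(q^2))
    if (nq < 1e-12) return(1e9)
    rmsd_given_rotation(P, Q, quat_to_rotmat(q / nq))
  }
  cands <- replicate(n_grid, random_quaternion())
  vals <- apply(cands, 2, objective)
  best <- Inf
  for (j in order(vals)[seq_len(n_polish)]) {
    fit <- optim(cands[, j], objective, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    fit <- optim(fit$par, objective, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Multi-start TM-score superposition oracle: maximize the raw TM sum over
# rigid motions directly, with Nelder-Mead over (rotation vector, translation)
# from many random rotation starts plus one centroid-aligned identity start.
tm_multistart_oracle <- function(P, Q, d0, Lnorm, n_starts = 50) {
  tm_of <- function(par) {
    theta <- sqrt(sum(par[1:3]^2))
    R <- if (theta < 1e-12) diag(3) else {
      k <- par[1:3] / theta
      Kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
      diag(3) + sin(theta) * Kx + (1 - cos(theta)) * (Kx %*% Kx)
    }
    d2 <- rowSums((sweep(P %*% t(R), 2, -par[4:6]) - Q)^2)
    sum(1 / (1 + d2 / d0^2)) / Lnorm
  }
  starts <- c(list(c(0, 0, 0, colMeans(Q) - colMeans(P))),
              lapply(seq_len(n_starts - 1), function(i) {
                q <- random_quaternion()
                ax <- q[2:4]; nax <- sqrt(sum(ax^2))
                ang <- 2 * acos(pmin(1, abs(q[1])))
                rv <- if (nax < 1e-12) c(0, 0, 0) else ax / nax * ang
                R0 <- quat_to_rotmat(q)
                c(rv, colMeans(Q) - colMeans(P %*% t(R0)))
              }))
  best <- -Inf
  for (s in starts) {
    fit <- optim(s, function(p) -tm_of(p), method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-12))
    fit <- optim(fit$par, function(p) -tm_of(p), method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-12))
    best <- max(best, -fit$value)
  }
  best
}

# O(n) recount of sensitivity-to-first-FP, written independently.
sensitivity_recount <- function(ranked_labels, total_tp) {
  seen_tp <- 0
  for (lab in ranked_labels) {
    if (lab == "FP") break
    if (lab == "TP") seen_tp <- seen_tp + 1
  }
  seen_tp / total_tp
}

# Apply a random rigid motion to a chain.
rigid_copy <- function(chain, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- random_rotation()
  t_vec <- rnorm(3, 0, 20)
  protein_chain(chain$chain_id, chain$sequence,
                sweep(chain$ca_coords %*% t(R), 2, -t_vec),
                chain$n_unmodelled)
}

# Minimal NPY writer (v1.0, little-endian float64, C order) for adapter tests.
write_npy <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(1), as.raw(0)), con)
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  header <- paste0(header, strrep(" ", pad), "\n")
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(t(m)), con, size = 8, endian = "little")
}

desk_fit_for_tests <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- make_family_dataset(synthetic_spec(
        n_families = 2L, members_per_family = 6L, length_range = c(40L, 48L),
        perturbation_sigmas = c(0, 0.4, 0.8, 1.2), seed = 5L))
      fit <- structembed_fit(ds$chains, ds$tm,
                             agg_config = desk_aggregator_config(seed = 3L),
                             config = train_config(epochs = 6L, pairs_per_epoch = 64L,
                                                   validation_fraction = 0.1, seed = 4L))
      cache <<- list(ds = ds, fit = fit)
    }
    cache
  }
})
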