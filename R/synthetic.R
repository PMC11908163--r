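AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate an idealized synthetic backbone scaffold
#'
#' Produces a CA-only chain on one of three idealized geometries:
#' \describe{
#'   \item{helix}{residue i at (r cos(i theta), r sin(i theta), i h) with
#'     r = 2.3 A, theta = 100 degrees, h = 1.5 A rise — the canonical
#'     alpha-helical CA spiral (adjacent CA-CA distance about 3.83 A).}
#'   \item{strand}{a pleated trace (3.3 i, 0.95 (-1)^i, 0), adjacent CA-CA
#'     distance about 3.81 A.}
#'   \item{coil}{a self-avoiding random walk with 3.8 A steps in which no
#'     non-adjacent pair comes closer than 4.0 A.}
#' }
#' The sequence is drawn uniformly over the 20 standard amino acids from
#' `seed`, so scaffolds are fully reproducible.
#'
#' @param kind `"helix"`, `"strand"`, or `"coil"`.
#' @param n_residues number of residues (at least 3).
#' @param seed integer seed for sequence (and, for coils, geometry).
#' @param chain_id chain identifier for the returned chain.
#' @return A [protein_chain].
#' @export
make_scaffold <- function(kind = c("helix", "strand", "coil"), n_residues, seed = 1L,
                          chain_id = "A") {
  kind <- match.arg(kind)
  if (n_residues < 3L) se_stop("validation_error", "n_residues must be >= 3")
  with_seed(seed, {
    seq1 <- paste(sample(AA20, n_residues, replace = TRUE), collapse = "")
    i <- seq_len(n_residues) - 1
    xyz <- switch(kind,
      helix = {
        theta <- 100 * pi / 180
        cbind(2.3 * cos(i * theta), 2.3 * sin(i * theta), 1.5 * i)
      },
      strand = cbind(3.3 * i, 0.95 * (-1)^i, 0),
      coil = coil_walk(n_residues)
    )
    protein_chain(chain_id, seq1, xyz)
  })
}

# Self-avoiding random walk: 3.8 A steps, non-adjacent pairs kept >= 4.0 A.
# Per-step rejection sampling with bounded restarts of the whole walk.
coil_walk <- function(n, step = 3.8, min_sep = 4.0,
                      max_tries = 60L, max_restarts = 200L) {
  for (restart in seq_len(max_restarts)) {
    xyz <- matrix(0, n, 3)
    ok <- TRUE
    for (k in 2:n) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        u <- stats::rnorm(3)
        cand <- xyz[k - 1, ] + step * u / sqrt(sum(u^2))
        if (k <= 2) { placed <- TRUE } else {
          prev <- xyz[seq_len(k - 2), , drop = FALSE]
          d2 <- rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2)
          placed <- all(d2 >= min_sep^2)
        }
        if (placed) { xyz[k, ] <- cand; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  se_stop("generation_error", "self-avoiding walk failed after %d restarts", max_restarts)
}

#' Perturb a chain with isotropic Gaussian coordinate noise
#'
#' Adds independent N(0, sigma^2) displacements to every coordinate of every
#' CA; the sequence is unchanged. Used to build families of structures whose
#' TM-score to the parent scaffold decays with `sigma`.
#'
#' @param chain a [protein_chain].
#' @param sigma noise standard deviation in Angstrom (>= 0).
#' @param seed integer seed.
#' @param chain_id optional new chain id (defaults to the input id).
#' @return A perturbed [protein_chain].
#' @export
perturb_chain <- function(chain, sigma, seed = 1L, chain_id = chain$chain_id) {
  validate_protein_chain(chain)
  if (sigma < 0) se_stop("validation_error", "sigma must be >= 0")
  L <- chain_length(chain)
  xyz <- chain$ca_coords + with_seed(seed, matrix(stats::rnorm(L * 3, 0, sigma), L, 3))
  protein_chain(chain_id, chain$sequence, xyz, chain$n_unmodelled)
}

#' Specification for a synthetic family dataset
#'
#' Describes a toy structural corpus: families built from one scaffold each,
#' with members perturbed at escalating noise scales, mimicking (at desk
#' scale) the construction of TM-score-labelled domain-pair training sets.
#'
#' @param n_families number of families.
#' @param members_per_family members per family (the first member is the
#'   unperturbed scaffold when the first sigma is 0).
#' @param length_range integer (min, max) residues; each family draws one
#'   length uniformly.
#' @param perturbation_sigmas noise scales in Angstrom, recycled across
#'   members in order.
#' @param scaffold_mix proportions of helix/strand/coil scaffolds (sums to 1).
#' @param seed integer seed controlling everything downstream.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_families = 3L, members_per_family = 8L,
                           length_range = c(50L, 70L),
                           perturbation_sigmas = c(0, 0.25, 0.5, 1, 1.5, 2.2, 3),
                           scaffold_mix = c(helix = 0.4, strand = 0.3, coil = 0.3),
                           seed = 1L) {
  if (n_families < 1L || members_per_family < 1L)
    se_stop("validation_error", "counts must be positive")
  if (any(perturbation_sigmas < 0)) se_stop("validation_error", "sigmas must be >= 0")
  if (abs(sum(scaffold_mix) - 1) > 1e-8)
    se_stop("validation_error", "scaffold_mix must sum to 1")
  if (length(length_range) != 2L || length_range[1] > length_range[2] || length_range[1] < 3L)
    se_stop("validation_error", "invalid length_range")
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 length_range = as.integer(length_range),
                 perturbation_sigmas = as.numeric(perturbation_sigmas),
                 scaffold_mix = scaffold_mix, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labelled synthetic family dataset with TM-score ground truth
#'
#' Each family is one scaffold ([make_scaffold]) plus members perturbed at
#' the spec's escalating sigmas ([perturb_chain]); all members of a family
#' share the scaffold length, so within-family TM-scores use the identity
#' correspondence, while cross-family pairs of unequal length use the
#' sliding-window correspondence of [tm_score_pair_max]. The full pairwise
#' max-normalized TM matrix is computed as ground truth.
#'
#' @param spec a [synthetic_spec].
#' @param compute_tm if `FALSE`, skip the TM matrix (returned as `NULL`).
#' @return A list with `chains` (named list of [protein_chain]),
#'   `families` (named character vector: chain id -> family id), and `tm`
#'   (symmetric matrix of pairwise `tm_max`, unit diagonal).
#' @export
make_family_dataset <- function(spec, compute_tm = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  kinds <- rep(names(spec$scaffold_mix),
               diff(round(cumsum(c(0, spec$scaffold_mix)) * spec$n_families)))
  if (length(kinds) < spec$n_families)
    kinds <- c(kinds, rep(names(spec$scaffold_mix)[1], spec$n_families - length(kinds)))
  lens <- with_seed(spec$seed,
                    sample(seq(spec$length_range[1], spec$length_range[2]),
                           spec$n_families, replace = TRUE))
  chains <- list(); families <- character(0)
  for (f in seq_len(spec$n_families)) {
    fam_id <- sprintf("F%02d", f)
    base_seed <- spec$seed * 1000L + f
    scaffold <- make_scaffold(kinds[f], lens[f], seed = base_seed)
    sigmas <- rep_len(spec$perturbation_sigmas, spec$members_per_family)
    for (m in seq_len(spec$members_per_family)) {
      id <- sprintf("%s_m%02d", fam_id, m)
      ch <- perturb_chain(scaffold, sigmas[m], seed = base_seed + 17L * m, chain_id = id)
      chains[[id]] <- ch
      families[id] <- fam_id
    }
  }
  tm <- NULL
  if (compute_tm) {
    ids <- names(chains)
    n <- length(ids)
    tm <- matrix(1, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      t <- tm_score_pair_max(chains[[i]], chains[[j]])$tm_max
      tm[i, j] <- t; tm[j, i] <- t
    }
  }
  list(chains = chains, families = families, tm = tm)
}

#' Build a cyclic-symmetric homomeric assembly from one chain
#'
#' Copy k (k = 0..n-1) of the centred chain is rotated about the z axis by
#' 2*pi*k/n and translated radially outward by `radius`, producing an ideal
#' C_n ring of 2 to 24 subunits. Chain ids are distinct letters. The
#' construction is deterministic; `seed` is accepted for API uniformity but
#' unused.
#'
#' @param chain a [protein_chain]; it is centred at its centroid first.
#' @param n_copies number of subunits, 2..24.
#' @param radius radial displacement in Angstrom.
#' @param seed unused; present for interface uniformity with the other
#'   generators.
#' @param assembly_id assembly identifier.
#' @return An [assembly] with `n_copies` chains.
#' @export
make_symmetric_assembly <- function(chain, n_copies, radius = 20, seed = 1L,
                                    assembly_id = "synthetic_assembly") {
  validate_protein_chain(chain)
  if (n_copies < 2L || n_copies > 24L)
    se_stop("validation_error", "n_copies must be in 2..24")
  xyz0 <- sweep(chain$ca_coords, 2, colMeans(chain$ca_coords))
  chains <- vector("list", n_copies)
  for (k in seq_len(n_copies)) {
    ang <- 2 * pi * (k - 1) / n_copies
    R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
    xyz <- xyz0 %*% t(R)
    xyz <- sweep(xyz, 2, radius * c(cos(ang), sin(ang), 0), "+")
    chains[[k]] <- protein_chain(LETTERS[k], chain$sequence, xyz, chain$n_unmodelled)
  }
  assembly(assembly_id, chains)
}
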