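#' Configuration for the residue embedder
#'
#' The embedder turns a chain into an L x `d_model` matrix of per-residue
#' vectors. Two sources are supported: the built-in rigid-motion-invariant
#' geometric featurizer (34 raw features projected to `d_model` by a fixed,
#' seeded random linear map — a self-contained stand-in for an external
#' protein language model), or externally computed per-residue embeddings
#' loaded from file (conventionally 1536-dimensional). `sequence_only = TRUE`
#' zeroes all geometry-derived features, leaving only the amino-acid one-hot
#' block — the "sequence embeddings" ablation.
#'
#' @param source `"geometric"` or `"external"`.
#' @param d_model embedding width (>= 8); default 64 for the geometric
#'   source, 1536 for external.
#' @param projection_seed seed for the fixed 34 -> d_model projection.
#' @param sequence_only ablation flag: drop structural features.
#' @return An object of class `embedder_config`.
#' @export
embedder_config <- function(source = c("geometric", "external"),
                            d_model = if (match.arg(source) == "external") 1536L else 64L,
                            projection_seed = 42L, sequence_only = FALSE) {
  source <- match.arg(source)
  if (d_model < 8L) se_stop("config_error", "d_model must be >= 8")
  structure(list(source = source, d_model = as.integer(d_model),
                 projection_seed = as.integer(projection_seed),
                 sequence_only = isTRUE(sequence_only)),
            class = "embedder_config")
}

N_GEOM_FEATURES <- 34L

#' Rigid-motion-invariant geometric residue features
#'
#' Per residue i (L x 34 in total):
#' \itemize{
#'   \item one-hot amino-acid identity over the 20 standard letters
#'     (unknown `"X"` gives a zero block) — 20 columns;
#'   \item sin/cos of the CA planar bend angle at (i-1, i, i+1) and of the
#'     CA pseudo-dihedral at (i-1, i, i+1, i+2), zero-padded at termini — 4;
#'   \item CA-CA distances d(i, i±k) for k = 1..4, clipped at 20 A and
#'     scaled to [0, 1], 0 where out of range — 8;
#'   \item neighbour counts within 8 A and 12 A (self excluded), scaled by
#'     1/L — 2.
#' }
#' All geometric quantities depend only on internal distances and proper
#' dihedrals, so the features are exactly invariant to rigid motions.
#'
#' @param chain a [protein_chain].
#' @return An L x 34 numeric matrix.
#' @export
geometric_featurize <- function(chain) {
  validate_protein_chain(chain)
  L <- chain_length(chain)
  X <- chain$ca_coords
  F <- matrix(0, L, N_GEOM_FEATURES)
  # one-hot AA
  aa_idx <- match(strsplit(chain$sequence, "")[[1]], AA20)
  ok <- !is.na(aa_idx)
  F[cbind(which(ok), aa_idx[ok])] <- 1
  if (L >= 3L) {
    for (i in 2:(L - 1)) {
      v1 <- X[i - 1, ] - X[i, ]; v2 <- X[i + 1, ] - X[i, ]
      cb <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cb)))
      F[i, 21] <- sin(ang); F[i, 22] <- cos(ang)
    }
  }
  if (L >= 4L) {
    for (i in 2:(L - 2)) {
      dh <- dihedral4(X[i - 1, ], X[i, ], X[i + 1, ], X[i + 2, ])
      F[i, 23] <- sin(dh); F[i, 24] <- cos(dh)
    }
  }
  for (k in 1:4) {
    idx <- if (L > k) seq_len(L - k) else integer(0)
    if (length(idx)) {
      d <- sqrt(rowSums((X[idx + k, , drop = FALSE] - X[idx, , drop = FALSE])^2))
      d <- pmin(d, 20) / 20
      F[idx, 24 + k] <- d          # d(i, i+k)
      F[idx + k, 28 + k] <- d      # d(i, i-k)
    }
  }
  D2 <- as.matrix(stats::dist(X))^2
  diag(D2) <- Inf
  F[, 33] <- rowSums(D2 < 64) / L    # 8 A
  F[, 34] <- rowSums(D2 < 144) / L   # 12 A
  F
}

dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Fixed projection matrix from the config seed; scaled so projected features
# have O(1) magnitude.
embedder_projection <- function(config) {
  with_seed(config$projection_seed,
            matrix(stats::rnorm(N_GEOM_FEATURES * config$d_model,
                                sd = 1 / sqrt(N_GEOM_FEATURES)),
                   N_GEOM_FEATURES, config$d_model))
}

#' Compute per-residue embedding sequences
#'
#' For the geometric source, featurizes each chain with
#' [geometric_featurize] and applies the fixed seeded projection; chains are
#' embedded independently, so a chain's embedding never depends on other
#' chains present (the property the assembly scheme relies on). For the
#' external source, `chain_or_chains` must be a file path accepted by
#' [load_external_embeddings].
#'
#' @param chain_or_chains a [protein_chain], a list of them, or (external
#'   source) a file path.
#' @param config an [embedder_config].
#' @param projection optional precomputed 34 x d_model projection matrix.
#' @return An object of class `residue_embedding` with `ids`, `matrix`
#'   (L_total x d_model) and `d_model`.
#' @export
embed_residues <- function(chain_or_chains, config = embedder_config(),
                           projection = NULL) {
  if (config$source == "external") {
    if (!is.character(chain_or_chains))
      se_stop("config_error", "external source expects a file path")
    return(load_external_embeddings(chain_or_chains, expected_d = config$d_model))
  }
  chains <- if (inherits(chain_or_chains, "protein_chain")) list(chain_or_chains)
            else chain_or_chains
  if (is.null(projection)) projection <- embedder_projection(config)
  if (!identical(dim(projection), c(N_GEOM_FEATURES, config$d_model)))
    se_stop("config_error", "projection must be %d x %d", N_GEOM_FEATURES, config$d_model)
  mats <- lapply(chains, function(ch) {
    F <- geometric_featurize(ch)
    if (config$sequence_only) F[, (21:N_GEOM_FEATURES)] <- 0
    F %*% projection
  })
  residue_embedding(vapply(chains, `[[`, "", "chain_id"), do.call(rbind, mats))
}

residue_embedding <- function(ids, matrix) {
  if (!all(is.finite(matrix)))
    se_stop("data_error", "non-finite residue embedding entries")
  structure(list(ids = ids, matrix = matrix, d_model = ncol(matrix)),
            class = "residue_embedding")
}

#' Load externally computed per-residue embeddings
#'
#' Accepts an L x D numeric array stored either as NPY (version 1.0/2.0,
#' C-order, float32/float64) or as a delimited text matrix (TSV/CSV, no
#' header). D must equal `expected_d` — by convention 1536, the width of
#' per-residue vectors from large structure-aware protein language models.
#'
#' @param path file path (`.npy`, `.tsv`, `.csv`, `.txt`).
#' @param expected_d required embedding width (default 1536).
#' @param id chain id to attach (defaults to the file stem).
#' @return A `residue_embedding`.
#' @export
load_external_embeddings <- function(path, expected_d = 1536L,
                                     id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) se_stop("data_error", "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "npy") read_npy_matrix(path)
       else as.matrix(utils::read.table(path, header = FALSE,
                                        sep = if (ext == "csv") "," else ""))
  if (!is.numeric(m)) se_stop("data_error", "'%s' is not a numeric array", path)
  if (ncol(m) != expected_d)
    se_stop("config_error", "embedding width %d, expected %d", ncol(m), expected_d)
  if (!all(is.finite(m)))
    se_stop("data_error", "non-finite entries in '%s'", path)
  dimnames(m) <- NULL
  residue_embedding(id, m)
}

# Minimal NPY reader: little-endian float32/float64, C-order, 2-D.
read_npy_matrix <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY"))))
    se_stop("data_error", "'%s' is not an NPY file", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
            readBin(con, "integer", 1, size = 4, endian = "little")
          else readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  if (length(shape) != 2L)
    se_stop("data_error", "NPY array must be 2-D, got shape (%s)", shape_s)
  size <- switch(descr, "<f8" = 8L, "<f4" = 4L,
                 se_stop("data_error", "unsupported NPY dtype '%s'", descr))
  vals <- readBin(con, "double", prod(shape), size = size, endian = "little")
  if (length(vals) != prod(shape))
    se_stop("data_error", "truncated NPY file '%s'", path)
  if (fortran) matrix(vals, shape[1], shape[2])
  else t(matrix(vals, shape[2], shape[1]))
}
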