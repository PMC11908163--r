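#' Aggregator network configuration
#'
#' The aggregator reduces an L x d_model residue-embedding sequence to one
#' fixed-length structure vector: `n_encoders` stacked transformer encoder
#' blocks (multi-head self-attention + feedforward, pre-norm, ReLU, **no
#' positional encoding**), a summation pooling over residues, then
#' `n_residual_blocks` fully connected residual blocks and a linear output
#' layer of width `d_out`. Without positional encodings the encoder stack is
#' permutation-equivariant, and sum pooling makes the final vector
#' permutation-invariant in the residue rows.
#'
#' Two profiles are used in practice: the full-scale profile
#' (`aggregator_config()` defaults: 6 encoders, d_model 1536, feedforward
#' width 3072, 12 residual blocks, d_out 1536, 8 heads) and a desk profile
#' ([desk_aggregator_config]) small enough to train on one CPU.
#'
#' @param n_encoders number of transformer encoder blocks (default 6).
#' @param d_model residue embedding width (default 1536).
#' @param n_heads attention heads (must divide d_model; default 8).
#' @param d_ff feedforward hidden width (default 3072).
#' @param n_residual_blocks number of post-pooling residual blocks (default 12).
#' @param d_out output vector width (default 1536).
#' @param seed initialization seed.
#' @return An object of class `aggregator_config`.
#' @export
aggregator_config <- function(n_encoders = 6L, d_model = 1536L, n_heads = 8L,
                              d_ff = 3072L, n_residual_blocks = 12L,
                              d_out = 1536L, seed = 1L) {
  if (any(c(n_encoders, d_model, n_heads, d_ff, n_residual_blocks, d_out) < 1L))
    se_stop("config_error", "all aggregator sizes must be positive")
  if (d_model %% n_heads != 0L)
    se_stop("config_error", "d_model (%d) must be divisible by n_heads (%d)",
            d_model, n_heads)
  structure(list(n_encoders = as.integer(n_encoders), d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 d_out = as.integer(d_out), activation = "relu",
                 positional_encoding = "none", seed = as.integer(seed)),
            class = "aggregator_config")
}

#' @rdname aggregator_config
#' @export
desk_aggregator_config <- function(seed = 1L) {
  aggregator_config(n_encoders = 2L, d_model = 64L, n_heads = 4L, d_ff = 128L,
                    n_residual_blocks = 3L, d_out = 64L, seed = seed)
}

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize an aggregator model
#'
#' Deterministically initializes all parameters from `config$seed`
#' (Glorot-uniform weights, zero biases, unit layer-norm gains). Layer norms
#' are placed pre-attention and pre-feedforward (pre-norm convention), with a
#' final layer norm before pooling; each residual block is
#' `s + W2 relu(W1 LN(s) + b1) + b2`.
#'
#' @param config an [aggregator_config].
#' @return A list of class `aggregator_model` with `config` and `params`.
#' @export
init_aggregator <- function(config) {
  stopifnot(inherits(config, "aggregator_config"))
  d <- config$d_model
  with_seed(config$seed, {
    enc <- lapply(seq_len(config$n_encoders), function(e) list(
      ln1_g = rep(1, d), ln1_b = rep(0, d),
      Wq = xavier(d, d), bq = rep(0, d),
      Wk = xavier(d, d), bk = rep(0, d),
      Wv = xavier(d, d), bv = rep(0, d),
      Wo = xavier(d, d), bo = rep(0, d),
      ln2_g = rep(1, d), ln2_b = rep(0, d),
      W1 = xavier(d, config$d_ff), b1 = rep(0, config$d_ff),
      W2 = xavier(config$d_ff, d), b2 = rep(0, d)
    ))
    res <- lapply(seq_len(config$n_residual_blocks), function(r) list(
      ln_g = rep(1, d), ln_b = rep(0, d),
      Wa = xavier(d, d), ba = rep(0, d),
      Wb = xavier(d, d), bb = rep(0, d)
    ))
    params <- list(enc = enc, lnf_g = rep(1, d), lnf_b = rep(0, d), res = res,
                   Wout = xavier(d, config$d_out), bout = rep(0, config$d_out))
    structure(list(config = config, params = params), class = "aggregator_model")
  })
}

#' @export
print.aggregator_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<aggregator_model> %d encoder block(s) (d_model %d, %d heads, ",
                     "d_ff %d), sum pooling, %d residual block(s), d_out %d\n"),
              cfg$n_encoders, cfg$d_model, cfg$n_heads, cfg$d_ff,
              cfg$n_residual_blocks, cfg$d_out))
  cat(sprintf("  parameters: %s\n",
              format(length(unlist(x$params)), big.mark = ",")))
  invisible(x)
}

LN_EPS <- 1e-5

ln_forward <- function(x, g, b) {
  x <- rbind(x)  # vectors become 1-row matrices
  mu <- rowMeans(x)
  xc <- x - mu
  inv_std <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv_std
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv_std = inv_std)
}

ln_backward <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv_std * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

relu <- function(x) { x[x < 0] <- 0; x }

# Forward pass through the aggregator; X is L x d_model. With cache = TRUE
# all intermediates needed for the backward pass are retained.
agg_forward <- function(model, X, cache = FALSE) {
  cfg <- model$config; p <- model$params
  if (ncol(X) != cfg$d_model)
    se_stop("config_error", "input width %d but model d_model is %d",
            ncol(X), cfg$d_model)
  H <- cfg$n_heads; dh <- cfg$d_model / H
  sc <- 1 / sqrt(dh)
  caches <- if (cache) vector("list", cfg$n_encoders)
  x <- X
  for (e in seq_len(cfg$n_encoders)) {
    pe <- p$enc[[e]]
    ln1 <- ln_forward(x, pe$ln1_g, pe$ln1_b); a <- ln1$y
    L <- nrow(a); d <- cfg$d_model
    QKV <- a %*% cbind(pe$Wq, pe$Wk, pe$Wv) +
      rep(c(pe$bq, pe$bk, pe$bv), each = L)
    Q <- QKV[, 1:d, drop = FALSE]
    K <- QKV[, (d + 1):(2 * d), drop = FALSE]
    V <- QKV[, (2 * d + 1):(3 * d), drop = FALSE]
    O <- matrix(0, L, d)
    A_list <- if (cache) vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE],
                                   K[, cols, drop = FALSE]) * sc)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      if (cache) A_list[[h]] <- A
    }
    attn <- O %*% pe$Wo + rep(pe$bo, each = L)
    x1 <- x + attn
    ln2 <- ln_forward(x1, pe$ln2_g, pe$ln2_b); bmat <- ln2$y
    Hpre <- bmat %*% pe$W1 + rep(pe$b1, each = L)
    Hrelu <- relu(Hpre)
    ff <- Hrelu %*% pe$W2 + rep(pe$b2, each = L)
    x2 <- x1 + ff
    if (cache) caches[[e]] <- list(x_in = x, ln1 = ln1, a = a, Q = Q, K = K, V = V,
                                   A = A_list, O = O, x1 = x1, ln2 = ln2,
                                   bmat = bmat, Hpre = Hpre, Hrelu = Hrelu)
    x <- x2
  }
  lnf <- ln_forward(x, p$lnf_g, p$lnf_b)
  s <- colSums(lnf$y)
  s_pool <- s
  res_caches <- if (cache) vector("list", cfg$n_residual_blocks)
  for (r in seq_len(cfg$n_residual_blocks)) {
    pr <- p$res[[r]]
    lnr <- ln_forward(s, pr$ln_g, pr$ln_b)
    hpre <- as.numeric(lnr$y %*% pr$Wa) + pr$ba
    hrelu <- relu(hpre)
    s_new <- s + as.numeric(hrelu %*% pr$Wb) + pr$bb
    if (cache) res_caches[[r]] <- list(s_in = s, lnr = lnr, hpre = hpre, hrelu = hrelu)
    s <- s_new
  }
  v <- as.numeric(s %*% p$Wout) + p$bout
  if (!cache) return(v)
  list(v = v, cache = list(enc = caches, x_final = x, lnf = lnf, s_pool = s_pool,
                           res = res_caches, s_out = s, L = nrow(X)))
}

# Backward pass: dv is the gradient of the loss wrt the output vector.
# Returns the flattened parameter gradient (same ordering as unlist(params))
# plus the gradient wrt the input rows (unused while the embedder is frozen).
agg_backward <- function(model, fwd, dv) {
  cfg <- model$config; p <- model$params
  H <- cfg$n_heads; dh <- cfg$d_model / H
  sc <- 1 / sqrt(dh)
  cc <- fwd$cache
  g <- list(enc = vector("list", cfg$n_encoders))
  s <- cc$s_out
  # output layer
  g$Wout <- outer(s, dv)
  g$bout <- dv
  ds <- as.numeric(p$Wout %*% dv)
  # residual blocks, reverse order
  g$res <- vector("list", cfg$n_residual_blocks)
  for (r in rev(seq_len(cfg$n_residual_blocks))) {
    pr <- p$res[[r]]; rc <- cc$res[[r]]
    dhrelu <- as.numeric(pr$Wb %*% ds)
    g$res[[r]] <- list(
      ln_g = NULL, ln_b = NULL,
      Wa = NULL, ba = NULL,
      Wb = outer(rc$hrelu, ds), bb = ds
    )
    dhpre <- dhrelu * (rc$hpre > 0)
    g$res[[r]]$Wa <- outer(as.numeric(rc$lnr$y), dhpre)
    g$res[[r]]$ba <- dhpre
    dlny <- matrix(as.numeric(pr$Wa %*% dhpre), 1)
    lb <- ln_backward(dlny, rc$lnr, pr$ln_g)
    g$res[[r]]$ln_g <- lb$dg
    g$res[[r]]$ln_b <- lb$db
    ds <- ds + as.numeric(lb$dx)
  }
  # sum pooling -> broadcast, then final LN
  dz <- matrix(ds, cc$L, cfg$d_model, byrow = TRUE)
  lbf <- ln_backward(dz, cc$lnf, p$lnf_g)
  g$lnf_g <- lbf$dg; g$lnf_b <- lbf$db
  dx <- lbf$dx
  # encoders, reverse order
  for (e in rev(seq_len(cfg$n_encoders))) {
    pe <- p$enc[[e]]; ec <- cc$enc[[e]]
    # feedforward sub-block
    dff <- dx
    dW2 <- crossprod(ec$Hrelu, dff)
    db2 <- colSums(dff)
    dHrelu <- tcrossprod(dff, pe$W2)
    dHpre <- dHrelu * (ec$Hpre > 0)
    dW1 <- crossprod(ec$bmat, dHpre)
    db1 <- colSums(dHpre)
    dbmat <- tcrossprod(dHpre, pe$W1)
    lb2 <- ln_backward(dbmat, ec$ln2, pe$ln2_g)
    dx1 <- dx + lb2$dx               # residual skip + ff path
    # attention sub-block
    dattn <- dx1
    dWo <- crossprod(ec$O, dattn)
    dbo <- colSums(dattn)
    dO <- tcrossprod(dattn, pe$Wo)
    dQ <- matrix(0, cc$L, cfg$d_model)
    dK <- matrix(0, cc$L, cfg$d_model)
    dV <- matrix(0, cc$L, cfg$d_model)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- ec$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, ec$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% ec$K[, cols, drop = FALSE] * sc
      dK[, cols] <- crossprod(dS, ec$Q[, cols, drop = FALSE]) * sc
    }
    dWq <- crossprod(ec$a, dQ); dbq <- colSums(dQ)
    dWk <- crossprod(ec$a, dK); dbk <- colSums(dK)
    dWv <- crossprod(ec$a, dV); dbv <- colSums(dV)
    da <- tcrossprod(dQ, pe$Wq) + tcrossprod(dK, pe$Wk) + tcrossprod(dV, pe$Wv)
    lb1 <- ln_backward(da, ec$ln1, pe$ln1_g)
    dx <- dx1 + lb1$dx               # residual skip + attention path
    g$enc[[e]] <- list(ln1_g = lb1$dg, ln1_b = lb1$db,
                       Wq = dWq, bq = dbq, Wk = dWk, bk = dbk,
                       Wv = dWv, bv = dbv, Wo = dWo, bo = dbo,
                       ln2_g = lb2$dg, ln2_b = lb2$db,
                       W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  }
  list(grad = g, dX = dx)
}

# Fast replacement for utils::relist on the params skeleton: one pass over
# the leaves, reconstructing each from a contiguous slice of the flat vector.
make_unflattener <- function(skeleton) {
  leaves <- list(); paths <- list()
  walk <- function(node, path) {
    if (is.list(node)) {
      for (i in seq_along(node)) walk(node[[i]], c(path, i))
    } else {
      leaves[[length(leaves) + 1L]] <<- node
      paths[[length(paths) + 1L]] <<- path
    }
  }
  walk(skeleton, integer(0))
  lens <- vapply(leaves, length, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  dims <- lapply(leaves, dim)
  function(flat) {
    out <- skeleton
    for (k in seq_along(paths)) {
      v <- flat[starts[k]:ends[k]]
      if (!is.null(dims[[k]])) dim(v) <- dims[[k]]
      out[[paths[[k]]]] <- v
    }
    out
  }
}

# Flatten a gradient tree in the canonical params order.
flatten_grad <- function(model, g) {
  ord <- list(enc = g$enc, lnf_g = g$lnf_g, lnf_b = g$lnf_b, res = g$res,
              Wout = g$Wout, bout = g$bout)
  unlist(ord, use.names = FALSE)
}

#' Aggregate a residue-embedding sequence into one structure vector
#'
#' Runs the aggregator forward pass. The output is invariant (to floating
#' tolerance) to any permutation of the input rows; zero-row padding is
#' rejected — the model has no masking semantics, inputs carry their true
#' length.
#'
#' @param res_emb a `residue_embedding` (see [embed_residues]).
#' @param model an `aggregator_model`.
#' @param id identifier for the returned embedding.
#' @return An object of class `structure_embedding` with `id` and `vector`.
#' @export
aggregate_embedding <- function(res_emb, model, id = paste(res_emb$ids, collapse = "+")) {
  stopifnot(inherits(model, "aggregator_model"))
  m <- if (inherits(res_emb, "residue_embedding")) res_emb$matrix else as.matrix(res_emb)
  v <- agg_forward(model, m)
  structure(list(id = id, vector = v), class = "structure_embedding")
}

#' Cosine similarity between structure embeddings
#'
#' @param a,b `structure_embedding` objects or plain numeric vectors of equal
#'   length (non-zero).
#' @return Cosine similarity in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  va <- if (inherits(a, "structure_embedding")) a$vector else as.numeric(a)
  vb <- if (inherits(b, "structure_embedding")) b$vector else as.numeric(b)
  if (length(va) != length(vb))
    se_stop("config_error", "dimension mismatch: %d vs %d", length(va), length(vb))
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) se_stop("degenerate_input_error", "zero vector")
  sum(va * vb) / (na * nb)
}

#' Save / load an aggregator model checkpoint
#'
#' Single-file archive (RDS) embedding the configuration, the parameters and
#' a format version tag.
#'
#' @param model an `aggregator_model` (or a fitted [structembed_fit] object,
#'   whose aggregator is saved).
#' @param path checkpoint file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "structembed")) model <- model$model
  stopifnot(inherits(model, "aggregator_model"))
  saveRDS(list(format = "structembed_checkpoint", version = 1L,
               config = unclass(model$config), params = model$params), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) se_stop("format_error", "cannot read checkpoint '%s'", path))
  if (!is.list(obj) || !identical(obj$format, "structembed_checkpoint"))
    se_stop("format_error", "'%s' is not a structembed checkpoint", path)
  if (!identical(obj$version, 1L))
    se_stop("format_error", "unsupported checkpoint version %s", obj$version)
  cfg <- do.call(aggregator_config,
                 obj$config[c("n_encoders", "d_model", "n_heads", "d_ff",
                              "n_residual_blocks", "d_out", "seed")])
  structure(list(config = cfg, params = obj$params), class = "aggregator_model")
}
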