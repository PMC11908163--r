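#' Build the training-pair table from a TM-score matrix
#'
#' One row per unordered pair of distinct chains, with the regression target
#' `tm_target = discretize_tm(tm_max)` — the maximum of the two
#' length-normalized TM-scores, rounded to the first decimal.
#'
#' @param ids character vector of chain ids.
#' @param tm_matrix symmetric matrix of pairwise `tm_max` values with
#'   dimnames covering `ids`.
#' @return A data.frame with columns `id_a`, `id_b`, `tm_target`.
#' @export
build_pair_dataset <- function(ids, tm_matrix) {
  if (is.null(dimnames(tm_matrix)) ||
      !all(ids %in% rownames(tm_matrix)) || !all(ids %in% colnames(tm_matrix)))
    se_stop("data_error", "tm_matrix must have dimnames covering all ids")
  n <- length(ids)
  if (n < 2L) se_stop("data_error", "need at least two chains")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tm <- tm_matrix[ids, ids][idx]
  if (any(!is.finite(tm)))
    se_stop("data_error", "missing TM value for some pair")
  data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
             tm_target = discretize_tm(pmin(1, pmax(0, tm))),
             stringsAsFactors = FALSE)
}

TM_BINS <- seq(0, 1, by = 0.1)

#' Sample a TM-bin-balanced batch of training pairs
#'
#' Draws each batch element by first picking one of the 11 discretized
#' TM-score bins uniformly at random *among the non-empty bins*, then a
#' uniform pair within that bin, with replacement — counteracting the heavy
#' skew of all-vs-all TM-score distributions toward low values.
#'
#' @param pairs data.frame from [build_pair_dataset].
#' @param batch_size number of pairs to draw.
#' @return Integer vector of row indices into `pairs` (length `batch_size`).
#' @export
sample_balanced_batch <- function(pairs, batch_size) {
  if (nrow(pairs) < 1L) se_stop("data_error", "no training pairs")
  if (batch_size < 1L) se_stop("validation_error", "batch_size must be >= 1")
  bin_of <- match(round(pairs$tm_target * 10), round(TM_BINS * 10))
  by_bin <- split(seq_len(nrow(pairs)), bin_of)
  bins <- sample.int(length(by_bin), batch_size, replace = TRUE)
  vapply(bins, function(b) {
    rows <- by_bin[[b]]
    rows[sample.int(length(rows), 1L)]
  }, 0L)
}

#' Twin-network loss
#'
#' Mean over the batch of `(cosine(emb_a, emb_b) - target)^2`, where both
#' embeddings come from the same shared-weight model. Symmetric in the two
#' embedding arguments.
#'
#' @param emb_a,emb_b numeric matrices (n_pairs x d) of paired structure
#'   embeddings, or single vectors.
#' @param targets numeric vector of discretized TM targets.
#' @return Scalar mean squared error.
#' @export
twin_loss <- function(emb_a, emb_b, targets) {
  emb_a <- rbind(emb_a); emb_b <- rbind(emb_b)
  if (nrow(emb_a) != nrow(emb_b) || nrow(emb_a) != length(targets))
    se_stop("validation_error", "mismatched batch shapes")
  na <- sqrt(rowSums(emb_a^2)); nb <- sqrt(rowSums(emb_b^2))
  cos <- rowSums(emb_a * emb_b) / (na * nb)
  mean((cos - targets)^2)
}

# d(loss)/d(emb_a), d/d(emb_b) for the twin loss on one pair.
cosine_grad_pair <- function(va, vb, target, n_pairs) {
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  cs <- sum(va * vb) / (na * nb)
  pre <- 2 * (cs - target) / n_pairs
  list(cos = cs,
       da = pre * (vb / (na * nb) - cs * va / na^2),
       db = pre * (va / (na * nb) - cs * vb / nb^2))
}

#' Area under the precision-recall curve
#'
#' Standard step integral of precision over recall: hits are sorted by score
#' descending, tied scores are collapsed into one operating point, and
#' `AUPRC = sum over points of (R_i - R_{i-1}) * P_i`. Used as the
#' checkpoint-selection metric on the validation pairs, with binary labels
#' `tm_target >= positive_threshold` and cosine similarities as scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (or 0/1) class labels; both classes must be present.
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || length(scores) < 1L)
    se_stop("metric_error", "scores and labels must be non-empty and matched")
  P <- sum(labels)
  if (P == 0L || P == length(labels))
    se_stop("metric_error", "validation set has a single class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # collapse tied scores into single operating points
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Validation AUPRC of a model on labelled pairs
#'
#' @param model an `aggregator_model`.
#' @param res_embs named list of `residue_embedding` objects (one per chain).
#' @param val_pairs data.frame from [build_pair_dataset].
#' @param positive_threshold TM target at or above which a pair is a
#'   positive (default 0.5, the conventional same-fold boundary).
#' @return AUPRC in [0, 1].
#' @export
validation_auprc <- function(model, res_embs, val_pairs, positive_threshold = 0.5) {
  if (nrow(val_pairs) < 1L) se_stop("metric_error", "empty validation set")
  vecs <- lapply(res_embs, function(re) agg_forward(model, re$matrix))
  scores <- mapply(function(a, b) cosine_similarity(vecs[[a]], vecs[[b]]),
                   val_pairs$id_a, val_pairs$id_b)
  auprc(scores, val_pairs$tm_target >= positive_threshold)
}

#' Group-aware k-fold split
#'
#' Partitions the *groups* (e.g. structural families), not the individual
#' ids, into k folds, so no group ever spans a training and a test fold —
#' the cross-validation design used to keep benchmark families out of the
#' training data.
#'
#' @param ids character vector of item ids.
#' @param group_labels group label per id.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return List of k character vectors of test ids (a partition of `ids`).
#' @export
grouped_split <- function(ids, group_labels, k, seed = 1L) {
  if (k < 2L) se_stop("split_error", "k must be >= 2")
  if (length(ids) != length(group_labels))
    se_stop("split_error", "every id needs a group label")
  groups <- unique(group_labels)
  if (length(groups) < k)
    se_stop("split_error", "fewer groups (%d) than folds (%d)", length(groups), k)
  shuffled <- with_seed(seed, sample(groups))
  fold_of_group <- rep_len(seq_len(k), length(shuffled))
  names(fold_of_group) <- shuffled
  lapply(seq_len(k), function(f) ids[fold_of_group[group_labels] == f])
}

#' Training configuration
#'
#' @param batch_size pairs per gradient step.
#' @param epochs training epochs.
#' @param pairs_per_epoch balanced pair draws per epoch.
#' @param learning_rate Adam base learning rate.
#' @param warmup_epochs linear warmup length (default 2).
#' @param validation_fraction fraction of pairs held out for AUPRC
#'   checkpointing (default 0.02).
#' @param validation_by `"pair"` (default) or `"group"`: whether the
#'   validation split is drawn over pairs or over whole families.
#' @param auprc_positive_threshold TM target defining the positive class.
#' @param seed seed for sampling and the validation split.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 30L, pairs_per_epoch = 256L,
                         learning_rate = 1e-3, warmup_epochs = 2L,
                         validation_fraction = 0.02, validation_by = c("pair", "group"),
                         auprc_positive_threshold = 0.5, seed = 1L) {
  validation_by <- match.arg(validation_by)
  if (validation_fraction <= 0 || validation_fraction >= 1)
    se_stop("config_error", "validation_fraction must be in (0, 1)")
  if (warmup_epochs >= epochs)
    se_stop("config_error", "warmup_epochs must be < epochs")
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 pairs_per_epoch = as.integer(pairs_per_epoch),
                 learning_rate = learning_rate, warmup_epochs = as.integer(warmup_epochs),
                 validation_fraction = validation_fraction, validation_by = validation_by,
                 auprc_positive_threshold = auprc_positive_threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Cosine-decay learning rate with linear warmup, at step granularity.
lr_schedule <- function(step, total_steps, warmup_steps, base_lr) {
  if (step <= warmup_steps && warmup_steps > 0) return(base_lr * step / warmup_steps)
  prog <- (step - warmup_steps) / max(1, total_steps - warmup_steps)
  base_lr * 0.5 * (1 + cos(pi * min(1, prog)))
}

#' Fit a structure-embedding model (twin-network training)
#'
#' Trains the aggregator as a twin network with shared weights: each batch
#' draws TM-bin-balanced pairs, embeds both members with the same model
#' state, and minimizes the mean squared error between the cosine similarity
#' of the two embeddings and the pair's discretized maximum TM-score, using
#' Adam under a cosine-decay schedule with linear warmup. The residue
#' embedder (the frozen language-model analogue) is fixed throughout. After
#' each epoch the AUPRC on the held-out validation pairs is computed and the
#' best-AUPRC parameter state is kept.
#'
#' @param chains named list of [protein_chain] objects.
#' @param tm_matrix symmetric pairwise `tm_max` matrix (dimnames = chain ids).
#' @param agg_config an [aggregator_config] (default: desk profile).
#' @param config a [train_config].
#' @param emb_config an [embedder_config] with `d_model` equal to
#'   `agg_config$d_model`.
#' @param groups optional named character vector (chain id -> group/family
#'   label), required when `config$validation_by == "group"`.
#' @param verbose print one line per epoch.
#' @return An object of class `structembed`: list with `model` (best-AUPRC
#'   `aggregator_model`), `final_model`, `history` (per-epoch data.frame with
#'   loss, validation AUPRC and learning rate), `best_epoch`, the configs,
#'   the frozen `projection`, and the training `chains`.
#' @seealso [predict.structembed()], [embed_assembly()]
#' @export
structembed_fit <- function(chains, tm_matrix,
                            agg_config = desk_aggregator_config(),
                            config = train_config(),
                            emb_config = embedder_config(d_model = agg_config$d_model),
                            groups = NULL, verbose = FALSE) {
  stopifnot(inherits(agg_config, "aggregator_config"),
            inherits(config, "train_config"))
  if (emb_config$d_model != agg_config$d_model)
    se_stop("config_error", "embedder d_model (%d) != aggregator d_model (%d)",
            emb_config$d_model, agg_config$d_model)
  ids <- names(chains)
  if (is.null(ids)) {
    ids <- vapply(chains, `[[`, "", "chain_id")
    names(chains) <- ids
  }
  pairs <- build_pair_dataset(ids, tm_matrix)
  projection <- embedder_projection(emb_config)
  res_embs <- lapply(chains, embed_residues, config = emb_config,
                     projection = projection)
  model <- init_aggregator(agg_config)
  skeleton <- model$params
  unflatten <- make_unflattener(skeleton)
  flat <- unlist(skeleton, use.names = FALSE)
  n_par <- length(flat)
  adam_m <- numeric(n_par); adam_v <- numeric(n_par)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  with_seed(config$seed, {
    # validation split
    if (config$validation_by == "pair") {
      n_val <- max(1L, round(config$validation_fraction * nrow(pairs)))
      val_idx <- sample.int(nrow(pairs), n_val)
    } else {
      if (is.null(groups) || is.null(names(groups)))
        se_stop("config_error", "validation_by = 'group' needs a named 'groups' vector")
      fams <- unique(groups[ids])
      val_fams <- sample(fams, max(1L, round(config$validation_fraction * length(fams))))
      in_val <- groups[pairs$id_a] %in% val_fams | groups[pairs$id_b] %in% val_fams
      val_idx <- which(in_val)
      if (length(val_idx) == 0L || length(val_idx) == nrow(pairs))
        se_stop("config_error", "group-level validation split is degenerate")
    }
    val_pairs <- pairs[val_idx, , drop = FALSE]
    train_pairs <- pairs[-val_idx, , drop = FALSE]
    if (length(unique(val_pairs$tm_target >= config$auprc_positive_threshold)) < 2L) {
      # ensure both classes in the validation set by borrowing one pair
      want <- !(val_pairs$tm_target[1] >= config$auprc_positive_threshold)
      cand <- which((train_pairs$tm_target >= config$auprc_positive_threshold) == want)[1]
      if (is.na(cand)) se_stop("metric_error", "cannot build two-class validation set")
      val_pairs <- rbind(val_pairs, train_pairs[cand, ])
      train_pairs <- train_pairs[-cand, , drop = FALSE]
    }
    steps_per_epoch <- max(1L, ceiling(config$pairs_per_epoch / config$batch_size))
    total_steps <- steps_per_epoch * config$epochs
    warmup_steps <- steps_per_epoch * config$warmup_epochs
    history <- data.frame(epoch = integer(), loss = numeric(), auprc = numeric(),
                          lr = numeric())
    best <- list(auprc = -Inf, params = model$params, epoch = 0L)
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      epoch_loss <- 0
      lr_now <- NA_real_
      for (st in seq_len(steps_per_epoch)) {
        step <- step + 1L
        rows <- sample_balanced_batch(train_pairs, config$batch_size)
        batch <- train_pairs[rows, , drop = FALSE]
        uids <- unique(c(batch$id_a, batch$id_b))
        fwds <- lapply(uids, function(id)
          agg_forward(model, res_embs[[id]]$matrix, cache = TRUE))
        names(fwds) <- uids
        dvs <- lapply(fwds, function(f) numeric(agg_config$d_out))
        loss <- 0
        for (r in seq_len(nrow(batch))) {
          a <- batch$id_a[r]; b <- batch$id_b[r]
          gr <- cosine_grad_pair(fwds[[a]]$v, fwds[[b]]$v, batch$tm_target[r],
                                 nrow(batch))
          loss <- loss + (gr$cos - batch$tm_target[r])^2
          dvs[[a]] <- dvs[[a]] + gr$da
          dvs[[b]] <- dvs[[b]] + gr$db
        }
        loss <- loss / nrow(batch)
        if (!is.finite(loss))
          se_stop("training_error", "non-finite loss at epoch %d", epoch)
        grad_flat <- numeric(n_par)
        for (id in uids) {
          if (all(dvs[[id]] == 0)) next
          bk <- agg_backward(model, fwds[[id]], dvs[[id]])
          grad_flat <- grad_flat + flatten_grad(model, bk$grad)
        }
        lr_now <- lr_schedule(step, total_steps, warmup_steps, config$learning_rate)
        adam_m <- b1 * adam_m + (1 - b1) * grad_flat
        adam_v <- b2 * adam_v + (1 - b2) * grad_flat^2
        mhat <- adam_m / (1 - b1^step)
        vhat <- adam_v / (1 - b2^step)
        flat <- flat - lr_now * mhat / (sqrt(vhat) + eps)
        model$params <- unflatten(flat)
        epoch_loss <- epoch_loss + loss
      }
      ap <- validation_auprc(model, res_embs, val_pairs,
                             config$auprc_positive_threshold)
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss = epoch_loss / steps_per_epoch,
                                           auprc = ap, lr = lr_now))
      # ties broken toward the later epoch: at equal validation AUPRC the
      # more-trained state has lower training loss
      if (ap >= best$auprc) best <- list(auprc = ap, params = model$params, epoch = epoch)
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  val AUPRC %.4f  lr %.2e\n",
                    epoch, epoch_loss / steps_per_epoch, ap, lr_now))
    }
    best_model <- structure(list(config = agg_config, params = best$params),
                            class = "aggregator_model")
    structure(list(model = best_model, final_model = model, history = history,
                   best_epoch = best$epoch, best_auprc = best$auprc,
                   agg_config = agg_config, train_config = config,
                   emb_config = emb_config, projection = projection,
                   chains = chains, train_pairs = train_pairs,
                   val_pairs = val_pairs, call = match.call()),
              class = "structembed")
  })
}
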