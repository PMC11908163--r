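#' @export
print.structembed <- function(x, ...) {
  cat("Structure-embedding model (twin-network TM-score regression)\n")
  cat(sprintf("  chains: %d   training pairs: %d   validation pairs: %d\n",
              length(x$chains), nrow(x$train_pairs), nrow(x$val_pairs)))
  cat(sprintf("  best validation AUPRC %.4f at epoch %d of %d\n",
              x$best_auprc, x$best_epoch, x$train_config$epochs))
  print(x$model)
  invisible(x)
}

#' @export
summary.structembed <- function(object, ...) {
  h <- object$history
  res <- residuals(object)
  out <- list(
    n_chains = length(object$chains),
    n_train_pairs = nrow(object$train_pairs),
    n_val_pairs = nrow(object$val_pairs),
    epochs = object$train_config$epochs,
    best_epoch = object$best_epoch,
    best_auprc = object$best_auprc,
    first_loss = h$loss[1], last_loss = h$loss[nrow(h)],
    train_rmse = sqrt(mean(res^2)),
    train_spearman = stats::cor(predict_pair_scores(object, object$train_pairs),
                                object$train_pairs$tm_target, method = "spearman")
  )
  class(out) <- "summary.structembed"
  out
}

#' @export
print.summary.structembed <- function(x, ...) {
  cat("Twin-network structure-embedding model\n")
  cat(sprintf("  %d chains, %d training / %d validation pairs, %d epochs\n",
              x$n_chains, x$n_train_pairs, x$n_val_pairs, x$epochs))
  cat(sprintf("  loss %.4f -> %.4f; best validation AUPRC %.4f (epoch %d)\n",
              x$first_loss, x$last_loss, x$best_auprc, x$best_epoch))
  cat(sprintf("  training pairs: RMSE(cosine, TM target) = %.4f, Spearman = %.4f\n",
              x$train_rmse, x$train_spearman))
  invisible(x)
}

predict_pair_scores <- function(object, pairs) {
  embs <- predict(object, object$chains[unique(c(pairs$id_a, pairs$id_b))])
  vapply(seq_len(nrow(pairs)), function(r)
    cosine_similarity(embs[pairs$id_a[r], ], embs[pairs$id_b[r], ]), 0)
}

#' Predict structure embeddings or pairwise similarity scores
#'
#' With `type = "embedding"` (default) returns one fixed-length embedding
#' vector per chain or assembly in `newdata`. With `type = "similarity"`,
#' `newdata` must be a two-column data.frame of id pairs referring to
#' `chains` (default: the training chains), and the predicted TM-score
#' proxies — cosine similarities — are returned.
#'
#' @param object a fitted `structembed` model.
#' @param newdata a [protein_chain], an [assembly], a list of either, or
#'   (for `type = "similarity"`) a data.frame with columns `id_a`, `id_b`.
#' @param type `"embedding"` or `"similarity"`.
#' @param chains chain pool for similarity prediction.
#' @param ... unused.
#' @return A numeric matrix (items x d_out, rownames = ids) or a numeric
#'   vector of cosine similarities.
#' @export
predict.structembed <- function(object, newdata = object$chains,
                                type = c("embedding", "similarity"),
                                chains = object$chains, ...) {
  type <- match.arg(type)
  if (type == "similarity") {
    stopifnot(is.data.frame(newdata), all(c("id_a", "id_b") %in% names(newdata)))
    embs <- predict(object, chains[unique(c(newdata$id_a, newdata$id_b))])
    return(vapply(seq_len(nrow(newdata)), function(r)
      cosine_similarity(embs[newdata$id_a[r], ], embs[newdata$id_b[r], ]), 0))
  }
  if (inherits(newdata, c("protein_chain", "assembly"))) newdata <- list(newdata)
  vecs <- lapply(newdata, function(item) {
    if (inherits(item, "assembly"))
      embed_assembly(item, object$emb_config, object$model,
                     projection = object$projection)$vector
    else
      aggregate_embedding(embed_residues(item, object$emb_config,
                                         projection = object$projection),
                          object$model)$vector
  })
  ids <- vapply(newdata, function(item)
    if (inherits(item, "assembly")) item$assembly_id else item$chain_id, "")
  out <- do.call(rbind, vecs)
  rownames(out) <- unname(ids)
  out
}

#' Residuals of the fitted similarity model
#'
#' Difference between the predicted cosine similarity and the discretized
#' TM-score target over the training pairs.
#'
#' @param object a fitted `structembed` model.
#' @param ... unused.
#' @return Numeric vector, one residual per training pair.
#' @export
residuals.structembed <- function(object, ...) {
  predict_pair_scores(object, object$train_pairs) - object$train_pairs$tm_target
}

#' Plot training history
#'
#' Two-panel base-graphics display: training loss and validation AUPRC per
#' epoch, with the checkpointed (best-AUPRC) epoch marked.
#'
#' @param x a fitted `structembed` model.
#' @param ... passed to [plot()].
#' @export
plot.structembed <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss", ...)
  plot(h$epoch, h$auprc, type = "l", xlab = "epoch", ylab = "validation AUPRC", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
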