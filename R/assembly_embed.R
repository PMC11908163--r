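#' Embed a multimeric assembly
#'
#' Computes residue-level embeddings for each chain **independently** (each
#' chain is embedded exactly as if it were alone — the embedder sees only
#' intra-chain geometry), row-concatenates them in the given chain order, and
#' aggregates the concatenated sequence with the trained model. Because the
#' aggregator carries no positional encoding and pools by summation, the
#' result is invariant to the order in which chains are listed.
#'
#' @param asm an [assembly].
#' @param emb_config an [embedder_config].
#' @param model an `aggregator_model` (or a fitted [structembed_fit] object).
#' @param projection optional precomputed embedder projection.
#' @return A `structure_embedding` for the whole assembly.
#' @export
embed_assembly <- function(asm, emb_config, model, projection = NULL) {
  stopifnot(inherits(asm, "assembly"))
  if (inherits(model, "structembed")) {
    if (is.null(projection)) projection <- model$projection
    if (missing(emb_config)) emb_config <- model$emb_config
    model <- model$model
  }
  if (emb_config$d_model != model$config$d_model)
    se_stop("config_error", "embedder d_model (%d) != aggregator d_model (%d)",
            emb_config$d_model, model$config$d_model)
  res <- embed_residues(asm$chains, emb_config, projection = projection)
  aggregate_embedding(res, model, id = asm$assembly_id)
}
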