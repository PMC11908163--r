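#' Vector store for structure embeddings
#'
#' Holds L2-normalized embedding vectors with unique string ids, supporting
#' exact top-k cosine search (inner product over unit vectors) and an
#' HNSW-based approximate index for large stores.
#'
#' @param ids optional character vector of ids.
#' @param vectors optional numeric matrix (one row per id); rows are
#'   L2-normalized at insertion.
#' @return An object of class `vector_store`.
#' @seealso [vs_add()], [search_exact()], [build_ann()], [search_ann()]
#' @export
vector_store <- function(ids = character(0), vectors = NULL) {
  store <- structure(list(ids = character(0), vectors = NULL, ann = NULL),
                     class = "vector_store")
  if (length(ids)) {
    stopifnot(!is.null(vectors), nrow(vectors) == length(ids))
    if (anyDuplicated(ids)) se_stop("key_error", "duplicate ids")
    nrm <- sqrt(rowSums(vectors^2))
    if (any(nrm == 0) || any(!is.finite(nrm)))
      se_stop("degenerate_input_error", "zero or non-finite vector")
    store$ids <- as.character(ids)
    store$vectors <- vectors / nrm
    dimnames(store$vectors) <- NULL
  }
  store
}

#' @export
print.vector_store <- function(x, ...) {
  cat(sprintf("<vector_store> %d vector(s)%s%s\n", length(x$ids),
              if (length(x$ids)) sprintf(" of dim %d", ncol(x$vectors)) else "",
              if (!is.null(x$ann)) sprintf(", HNSW index (M=%d, ef_construction=%d)",
                                           x$ann$M, x$ann$ef_construction) else ""))
  invisible(x)
}

#' Add one embedding to a vector store
#'
#' The vector is L2-normalized before storage. Adding invalidates any
#' previously built approximate index (it must be rebuilt).
#'
#' @param store a [vector_store].
#' @param id unique string id.
#' @param embedding numeric vector or `structure_embedding` (non-zero).
#' @return The updated store.
#' @export
vs_add <- function(store, id, embedding) {
  stopifnot(inherits(store, "vector_store"))
  v <- if (inherits(embedding, "structure_embedding")) embedding$vector
       else as.numeric(embedding)
  if (id %in% store$ids) se_stop("key_error", "id '%s' already present", id)
  nrm <- sqrt(sum(v^2))
  if (!is.finite(nrm) || nrm == 0)
    se_stop("degenerate_input_error", "zero or non-finite vector for '%s'", id)
  if (!is.null(store$vectors) && length(v) != ncol(store$vectors))
    se_stop("config_error", "dimension mismatch: %d vs %d", length(v), ncol(store$vectors))
  store$vectors <- rbind(store$vectors, v / nrm)
  dimnames(store$vectors) <- NULL
  store$ids <- c(store$ids, id)
  store$ann <- NULL
  store
}

normalize_query <- function(store, query) {
  q <- if (inherits(query, "structure_embedding")) query$vector else as.numeric(query)
  if (length(q) != ncol(store$vectors))
    se_stop("config_error", "query dimension %d, store dimension %d",
            length(q), ncol(store$vectors))
  nrm <- sqrt(sum(q^2))
  if (!is.finite(nrm) || nrm == 0) se_stop("degenerate_input_error", "zero query vector")
  q / nrm
}

#' Exact top-k cosine search
#'
#' Brute-force inner-product scan over the unit-normalized store, sorted by
#' score descending with deterministic lexicographic id tie-break, optionally
#' excluding one id (conventionally the query itself).
#'
#' @param store a non-empty [vector_store].
#' @param query numeric vector or `structure_embedding`.
#' @param k number of results (capped at the store size).
#' @param exclude optional id to drop from the results (self-comparison).
#' @return data.frame with columns `id` and `score`, ordered best-first.
#' @export
search_exact <- function(store, query, k, exclude = NULL) {
  stopifnot(inherits(store, "vector_store"))
  if (length(store$ids) == 0L) se_stop("state_error", "empty store")
  if (k < 1L) se_stop("validation_error", "k must be >= 1")
  q <- normalize_query(store, query)
  scores <- as.numeric(store$vectors %*% q)
  keep <- if (is.null(exclude)) seq_along(store$ids) else which(store$ids != exclude)
  ord <- keep[order(-scores[keep], store$ids[keep])]
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(id = store$ids[ord], score = scores[ord], stringsAsFactors = FALSE)
}

#' Build / query the HNSW approximate index
#'
#' `build_ann` constructs a deterministic Hierarchical Navigable Small World
#' graph over the stored unit vectors; `search_ann` answers approximate
#' top-k cosine queries through it. At the defaults (M = 16,
#' ef_construction = 200, ef_search = 128) recall\@10 against [search_exact]
#' is expected to exceed 0.95 on random unit vectors; raising `ef_search`
#' trades speed for recall.
#'
#' @param store a non-empty [vector_store].
#' @param M maximum neighbours per node on upper layers (layer 0 allows 2M).
#' @param ef_construction beam width during construction.
#' @param seed seed for the level assignment.
#' @return `build_ann`: the store with `ann` populated.
#' @export
build_ann <- function(store, M = 16L, ef_construction = 200L, seed = 1L) {
  stopifnot(inherits(store, "vector_store"))
  if (length(store$ids) == 0L) se_stop("state_error", "empty store")
  g <- hnsw_build_cpp(store$vectors, as.integer(M), as.integer(ef_construction),
                      as.integer(seed))
  store$ann <- g
  store
}

#' @rdname build_ann
#' @param query numeric vector or `structure_embedding`.
#' @param k number of results.
#' @param ef_search beam width at query time (>= k; default 128).
#' @param exclude optional id to drop.
#' @return `search_ann`: data.frame with `id`, `score`.
#' @export
search_ann <- function(store, query, k, ef_search = 128L, exclude = NULL) {
  stopifnot(inherits(store, "vector_store"))
  if (is.null(store$ann)) se_stop("state_error", "no ANN index built; call build_ann()")
  q <- normalize_query(store, query)
  k_fetch <- min(if (is.null(exclude)) k else k + 1L, length(store$ids))
  idx <- hnsw_search_cpp(store$vectors, store$ann, matrix(q, 1),
                         as.integer(k_fetch), as.integer(max(ef_search, k_fetch)))[1, ]
  idx <- idx[!is.na(idx)]
  if (!is.null(exclude)) idx <- idx[store$ids[idx] != exclude]
  idx <- idx[seq_len(min(k, length(idx)))]
  scores <- as.numeric(store$vectors[idx, , drop = FALSE] %*% q)
  # HNSW returns by distance; enforce the same deterministic tie-break as exact
  ord <- order(-scores, store$ids[idx])
  data.frame(id = store$ids[idx][ord], score = scores[ord], stringsAsFactors = FALSE)
}

STORE_VERSION <- 1L

#' Save / load a vector store
#'
#' Single-file archive preserving ids, vectors bit-exactly, and the ANN graph
#' and its parameters. Files with a different format tag or version are
#' rejected.
#'
#' @param store a [vector_store].
#' @param path file path.
#' @return `save_store`: `path` invisibly; `load_store`: the store.
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "vector_store"))
  saveRDS(list(format = "structembed_store", version = STORE_VERSION,
               ids = store$ids, vectors = store$vectors, ann = store$ann), path)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) se_stop("format_error", "cannot read store '%s'", path))
  if (!is.list(obj) || !identical(obj$format, "structembed_store"))
    se_stop("format_error", "'%s' is not a structembed vector store", path)
  if (!identical(obj$version, STORE_VERSION))
    se_stop("format_error", "unsupported store version %s (expected %d)",
            obj$version, STORE_VERSION)
  store <- structure(list(ids = obj$ids, vectors = obj$vectors, ann = obj$ann),
                     class = "vector_store")
  store
}
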