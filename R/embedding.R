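#' Node embedding matrix
#'
#' A numeric matrix with one row per node (node ids as rownames) and one
#' column per embedding dimension.
#'
#' @param mat Numeric matrix with node ids as rownames.
#' @return An object of class `"node_embedding"`.
#' @export
node_embedding <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("node embedding needs node ids as rownames")
  if (anyDuplicated(rownames(mat))) stop("duplicate node id in embedding")
  if (!all(is.finite(mat))) stop("non-finite embedding entries")
  structure(mat, class = c("node_embedding", "matrix", "array"))
}

#' @export
print.node_embedding <- function(x, ...) {
  cat("<node_embedding>", nrow(x), "nodes x", ncol(x), "dims\n")
  invisible(x)
}

#' Tidy a node embedding into a long tibble
#' @param x A `node_embedding`.
#' @param ... Unused.
#' @return A tibble with columns `node_id`, `dimension`, `value`.
#' @export
tidy.node_embedding <- function(x, ...) {
  tibble::tibble(
    node_id = rep(rownames(x), times = ncol(x)),
    dimension = rep(seq_len(ncol(x)), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' Train skip-gram negative-sampling embeddings on a walk corpus
#'
#' Treats each walk as a sentence and maximises the agreement of co-occurring
#' (center, context) node pairs within a window against `negatives` noise
#' nodes drawn from the unigram^0.75 distribution of the corpus, by
#' stochastic gradient descent with a linearly decaying learning rate.
#' Training is single-threaded and bit-reproducible under a fixed seed.
#'
#' @param corpus A `walk_corpus` from [generate_walks()].
#' @param dim Embedding dimension (>= 2), default 100.
#' @param window Context window half-width.
#' @param negatives Negative samples per observed pair.
#' @param epochs Passes over the corpus.
#' @param learning_rate Initial learning rate (linear decay to 1e-4 of it).
#' @param seed Integer seed.
#' @return A `node_embedding` with one row per node observed in the corpus
#'   (rows ordered by node id) and attribute `epoch_loss`, the mean
#'   negative-sampling loss per epoch.
#' @export
train_skipgram <- function(corpus, dim = 100, window = 10, negatives = 5,
                           epochs = 5, learning_rate = 0.025, seed = 1L) {
  stopifnot(inherits(corpus, "walk_corpus"), dim >= 2, window >= 1,
            negatives >= 1, epochs >= 1, learning_rate > 0)
  if (length(corpus$walks) == 0) stop("empty walk corpus")
  vocab <- sort(unique(unlist(corpus$walks)))
  walks0 <- lapply(corpus$walks, function(w) match(w, vocab) - 1L)
  fit <- sgns_train_cpp(walks0, length(vocab), as.integer(dim),
                        as.integer(window), as.integer(negatives),
                        as.integer(epochs), learning_rate, as.double(seed))
  emb <- fit$embedding
  rownames(emb) <- vocab
  out <- node_embedding(emb)
  attr(out, "epoch_loss") <- as.numeric(fit$epoch_loss)
  out
}
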