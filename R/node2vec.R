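#' Second-order random-walk transition distribution
#'
#' Probability of stepping from `curr_node` to each node of the graph, given
#' that the walk arrived from `prev_node`. Each neighbour's edge weight is
#' multiplied by the node2vec bias: `1/p` for returning to `prev_node`, 1 for
#' neighbours at distance one from `prev_node`, `1/q` for neighbours at
#' distance two; the result is normalised to sum to one. The unit diagonal of
#' a similarity graph is not an edge: walks never stay in place.
#'
#' @param prev_node,curr_node Node ids; `prev_node = NULL` gives the
#'   first-order (weight-proportional) distribution used for the first step.
#' @param graph A [similarity_graph()].
#' @param p,q Return and in-out bias parameters (> 0).
#' @return A named probability vector over all nodes of the graph (zero for
#'   non-neighbours of `curr_node`).
#' @export
transition_distribution <- function(prev_node, curr_node, graph, p = 1, q = 1) {
  stopifnot(p > 0, q > 0)
  w <- unclass(graph)
  diag(w) <- 0
  ids <- rownames(w)
  ci <- match(curr_node, ids)
  if (is.na(ci)) stop("unknown node: ", curr_node)
  wr <- w[ci, ]
  if (all(wr == 0)) stop("node has no positive-weight neighbour: ", curr_node)
  if (!is.null(prev_node)) {
    pi_ <- match(prev_node, ids)
    if (is.na(pi_)) stop("unknown node: ", prev_node)
    alpha <- ifelse(seq_along(ids) == pi_, 1 / p,
                    ifelse(w[pi_, ] > 0, 1, 1 / q))
    wr <- wr * alpha
  }
  wr / sum(wr)
}

#' Generate a biased random-walk corpus
#'
#' Runs `walks_per_node` truncated second-order random walks of length
#' `walk_length` from every non-isolated node. The first step of each walk is
#' weight-proportional; subsequent steps follow the node2vec bias of
#' [transition_distribution()]. Start-node order is shuffled per pass. Nodes
#' are indexed by sorted id internally, so the corpus depends on the set of
#' nodes and the seed only, not on insertion order.
#'
#' @param graph A [similarity_graph()].
#' @param p,q node2vec bias parameters.
#' @param walks_per_node Walks started from each node (>= 1).
#' @param walk_length Maximum walk length (>= 2).
#' @param seed Integer seed; identical seed gives an identical corpus.
#' @return An object of class `"walk_corpus"`: a list with `walks` (list of
#'   node-id character vectors) and `kind` (the source graph kind).
#' @export
generate_walks <- function(graph, p = 1, q = 1, walks_per_node = 10,
                           walk_length = 80, seed = 1L) {
  stopifnot(inherits(graph, "similarity_graph"),
            p > 0, q > 0, walks_per_node >= 1, walk_length >= 2)
  w <- unclass(graph)
  ord <- order(rownames(w))
  w <- w[ord, ord]
  diag(w) <- 0
  ids <- rownames(w)
  n <- length(ids)
  nb <- lapply(seq_len(n), function(i) which(w[i, ] > 0))
  isolated <- which(lengths(nb) == 0)
  if (length(isolated) == n) stop("graph has no edges")
  if (length(isolated) > 0) {
    warning("skipping ", length(isolated), " isolated node(s): ",
            paste(utils::head(ids[isolated], 5), collapse = ", "))
  }
  active <- setdiff(seq_len(n), isolated)
  adj <- w > 0
  walks <- vector("list", length(active) * walks_per_node)
  k <- 0L
  old <- .Random.seed_guard(seed)
  on.exit(old())
  for (pass in seq_len(walks_per_node)) {
    for (start in sample(active)) {
      walk <- integer(walk_length)
      walk[1] <- start
      nbs <- nb[[start]]
      wts <- w[start, nbs]
      walk[2] <- if (length(nbs) == 1) nbs else nbs[sample.int(length(nbs), 1, prob = wts)]
      step <- 2L
      while (step < walk_length) {
        prev <- walk[step - 1L]; curr <- walk[step]
        nbs <- nb[[curr]]
        alpha <- ifelse(nbs == prev, 1 / p, ifelse(adj[prev, nbs], 1, 1 / q))
        pr <- w[curr, nbs] * alpha
        step <- step + 1L
        walk[step] <- if (length(nbs) == 1) nbs else nbs[sample.int(length(nbs), 1, prob = pr)]
      }
      k <- k + 1L
      walks[[k]] <- ids[walk]
    }
  }
  structure(list(walks = walks, kind = attr(graph, "kind")),
            class = "walk_corpus")
}

# evaluate expr-free seed scoping: set the RNG and return a restore closure
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat("<walk_corpus>", length(x$walks), "walks over",
      length(unique(unlist(x$walks))), "nodes (", x$kind, "graph )\n")
  invisible(x)
}

#' Embed a similarity graph with node2vec
#'
#' Composition of [generate_walks()] and [train_skipgram()]: biased random
#' walks over the weighted graph are treated as sentences and node vectors
#' are learned with skip-gram negative sampling.
#'
#' @param graph A [similarity_graph()].
#' @param config A [pipeline_config()] supplying the walk and skip-gram
#'   hyperparameters.
#' @param seed Integer seed for this embedding stage; defaults to a child
#'   seed of `config$seed` keyed by the graph kind.
#' @return A `node_embedding` matrix (nodes x `config$embedding_dim`).
#' @export
embed_graph <- function(graph, config = pipeline_config(), seed = NULL) {
  kind <- attr(graph, "kind")
  seed <- seed %||% child_seed(config$seed, paste0("embed:", kind))
  corpus <- generate_walks(graph, p = config$p, q = config$q,
                           walks_per_node = config$walks_per_node,
                           walk_length = config$walk_length,
                           seed = child_seed(seed, "walks"))
  emb <- train_skipgram(corpus, dim = config$embedding_dim,
                        window = config$window, negatives = config$negatives,
                        epochs = config$epochs,
                        learning_rate = config$learning_rate,
                        seed = child_seed(seed, "sgns"))
  missing <- setdiff(sort(node_ids(graph)), node_ids(emb))
  if (length(missing) > 0) {
    warning("nodes absent from the walk corpus have no embedding: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  emb
}
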