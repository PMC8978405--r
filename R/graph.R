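#' Weighted similarity graph
#'
#' A similarity graph is a complete weighted undirected graph over drugs or
#' proteins, stored as a symmetric matrix of weights in `[0, 1]` with a unit
#' diagonal. It is the input of the node-embedding stage.
#'
#' @param weights Square numeric matrix of similarities; dimnames supply the
#'   node ids unless `node_ids` is given.
#' @param kind `"drug"` or `"protein"`.
#' @param node_ids Optional character vector of node ids.
#' @param tol Tolerance for symmetry / range checks (entries are symmetrised
#'   as `(M + t(M)) / 2` and the diagonal is forced to exactly 1).
#'
#' @return An object of class `"similarity_graph"`: the weight matrix with
#'   attributes `kind` and node ids as dimnames.
#' @export
#' @examples
#' w <- matrix(c(1, .4, .4, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' g <- similarity_graph(w, "drug")
#' node_ids(g)
similarity_graph <- function(weights, kind = c("drug", "protein"),
                             node_ids = NULL, tol = 1e-8) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("similarity matrix must be square, got ", nrow(weights), " x ", ncol(weights))
  }
  if (!is.null(node_ids)) dimnames(weights) <- list(node_ids, node_ids)
  ids <- rownames(weights)
  if (is.null(ids)) stop("node ids are required (dimnames or `node_ids`)")
  if (anyDuplicated(ids)) {
    stop("duplicate node id: ", ids[duplicated(ids)][1])
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol) stop("matrix is asymmetric beyond tolerance (max |M - t(M)| = ", signif(asym, 3), ")")
  weights <- (weights + t(weights)) / 2
  bad <- which(weights < -tol | weights > 1 + tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("similarity out of [0,1] at (", ids[bad[1, 1]], ", ", ids[bad[1, 2]],
         "): ", weights[bad[1, , drop = FALSE]])
  }
  weights[weights < 0] <- 0
  weights[weights > 1] <- 1
  diag(weights) <- 1
  structure(weights, kind = kind, class = c("similarity_graph", "matrix", "array"))
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("<similarity_graph> kind =", attr(x, "kind"), "|", nrow(x), "nodes\n")
  cat("  mean off-diagonal weight:",
      signif(mean(x[upper.tri(x)]), 4), "\n")
  invisible(x)
}

#' Node ids of a similarity graph or embedding
#' @param x A `similarity_graph` or `node_embedding`.
#' @return Character vector of node ids.
#' @export
node_ids <- function(x) rownames(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a similarity graph into an edge list
#'
#' @param x A `similarity_graph`.
#' @param ... Unused.
#' @return A tibble with one row per unordered node pair: `node_a`, `node_b`,
#'   `weight`.
#' @export
tidy.similarity_graph <- function(x, ...) {
  ids <- node_ids(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    node_a = ids[ut[, 1]],
    node_b = ids[ut[, 2]],
    weight = x[ut]
  )
}

#' Drop weak edges from a similarity graph
#'
#' Sets every off-diagonal weight below `min_weight` to zero. The diagonal is
#' untouched. Nodes left without any positive-weight edge are reported with a
#' warning, since they cannot be visited by random walks.
#'
#' @param graph A `similarity_graph`.
#' @param min_weight Threshold in `[0, 1)`; edges with weight strictly below
#'   it are removed.
#' @return A `similarity_graph` with the same nodes.
#' @export
sparsify <- function(graph, min_weight) {
  stopifnot(inherits(graph, "similarity_graph"),
            min_weight >= 0, min_weight <= 1)
  w <- unclass(graph)
  keep_diag <- diag(w)
  w[w < min_weight] <- 0
  diag(w) <- keep_diag
  off <- w
  diag(off) <- 0
  isolated <- rownames(w)[rowSums(off > 0) == 0]
  if (length(isolated) > 0 && length(isolated) < nrow(w)) {
    warning("sparsify isolated ", length(isolated), " node(s): ",
            paste(utils::head(isolated, 5), collapse = ", "),
            if (length(isolated) > 5) ", ..." else "")
  }
  similarity_graph(w, attr(graph, "kind"))
}
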