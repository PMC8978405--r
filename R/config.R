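#' Pipeline configuration
#'
#' Collects every tunable parameter of the DTI link-prediction pipeline in one
#' validated list: embedding dimension and walk/skip-gram hyperparameters,
#' the activity threshold used to label bioactivity records, the data-split
#' geometry, the boosted-tree hyperparameters, and the master seed from which
#' all per-stage seeds are derived.
#'
#' @param embedding_dim Dimension `n` of each node embedding; a drug-target
#'   pair is represented by a `2n`-vector. Default 100.
#' @param p,q node2vec return and in-out bias parameters (both > 0).
#' @param walks_per_node,walk_length Random-walk budget per node and length of
#'   each walk.
#' @param window Skip-gram context window half-width.
#' @param negatives Negative samples per observed (center, context) pair.
#' @param epochs,learning_rate Skip-gram training epochs and initial learning
#'   rate (linearly decayed).
#' @param activity_threshold pChEMBL value at or above which a measured
#'   activity is labelled positive. Default 5.5.
#' @param probability_threshold Minimum predicted probability for a pair to be
#'   reported as a repurposing candidate. Default 0.99.
#' @param external_fraction Fraction of labelled pairs held out once as the
#'   external test set. Default 0.1.
#' @param folds,repeats Internal cross-validation geometry. Defaults 10 and 5.
#' @param beta Beta of the f-beta selection metric; `NULL` picks 2 when
#'   negatives are sampled from unknown pairs and 1 when they are
#'   experimentally validated.
#' @param max_depth,subsample,min_child_weight,gamma Boosted-tree
#'   hyperparameters (defaults 4, 1, 2, 0.8).
#' @param n_estimators Maximum boosting rounds (early stopping may use fewer).
#' @param classifier_learning_rate Shrinkage (eta) of the boosted ensemble.
#' @param grid Named list of candidate hyperparameter values searched within
#'   each cross-validation repeat, e.g. `list(classifier_learning_rate =
#'   c(0.1, 0.3))`.
#' @param seed Master integer seed; see [child_seed()].
#'
#' @return A validated list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 1)
#' cfg$embedding_dim
pipeline_config <- function(embedding_dim = 100,
                            p = 1, q = 1,
                            walks_per_node = 10, walk_length = 80,
                            window = 10, negatives = 5,
                            epochs = 5, learning_rate = 0.025,
                            activity_threshold = 5.5,
                            probability_threshold = 0.99,
                            external_fraction = 0.1,
                            folds = 10, repeats = 5,
                            beta = NULL,
                            max_depth = 4, subsample = 1.0,
                            min_child_weight = 2, gamma = 0.8,
                            n_estimators = 200,
                            classifier_learning_rate = 0.1,
                            grid = list(classifier_learning_rate = c(0.1, 0.3)),
                            seed = 1L) {
  cfg <- list(
    embedding_dim = as.integer(embedding_dim),
    p = p, q = q,
    walks_per_node = as.integer(walks_per_node),
    walk_length = as.integer(walk_length),
    window = as.integer(window), negatives = as.integer(negatives),
    epochs = as.integer(epochs), learning_rate = learning_rate,
    activity_threshold = activity_threshold,
    probability_threshold = probability_threshold,
    external_fraction = external_fraction,
    folds = as.integer(folds), repeats = as.integer(repeats),
    beta = beta,
    max_depth = as.integer(max_depth), subsample = subsample,
    min_child_weight = min_child_weight, gamma = gamma,
    n_estimators = as.integer(n_estimators),
    classifier_learning_rate = classifier_learning_rate,
    grid = grid,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$embedding_dim >= 2,
    cfg$p > 0, cfg$q > 0,
    cfg$walks_per_node >= 1, cfg$walk_length >= 2,
    cfg$window >= 1, cfg$negatives >= 1, cfg$epochs >= 1,
    cfg$learning_rate > 0,
    cfg$activity_threshold > 0,
    cfg$probability_threshold >= 0, cfg$probability_threshold <= 1,
    cfg$external_fraction > 0, cfg$external_fraction < 1,
    cfg$folds >= 2, cfg$repeats >= 1,
    is.null(cfg$beta) || cfg$beta > 0,
    cfg$max_depth >= 1,
    cfg$subsample > 0, cfg$subsample <= 1
  )
  structure(cfg, class = "pipeline_config")
}

#' Derive a per-stage child seed from the master seed
#'
#' Every stochastic stage (walk generation, skip-gram initialisation, negative
#' sampling, data splitting, classifier training) draws its own seed from the
#' master seed and a stage name, so stages are reproducible independently and
#' reordering stages never silently changes results.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' child_seed(1, "walks:drug")
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  out <- ((as.double(seed) %% 2147483647) * 48271) %% 2147483647
  out <- (out + h * 7919 + 1) %% 2147483647
  as.integer(out + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
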