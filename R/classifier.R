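#' Boosted-tree classifier specification
#'
#' Hyperparameters of the gradient-boosted tree link classifier. The
#' defaults are the pipeline's reference values: maximum tree depth 4,
#' subsample ratio 1, minimum child weight 2, and split-regularisation gamma
#' 0.8; the shrinkage (learning rate) is left as a grid dimension. The number
#' of boosting rounds defaults to 200 with early stopping (patience 20) on
#' held-out log-loss whenever an evaluation set is available.
#'
#' @param max_depth Maximum tree depth (>= 1).
#' @param subsample Row subsample ratio in (0, 1].
#' @param min_child_weight Minimum sum of instance weights in a child.
#' @param gamma Minimum loss reduction required to make a split.
#' @param n_estimators Maximum boosting rounds.
#' @param learning_rate Shrinkage (eta).
#' @param patience Early-stopping rounds when an evaluation set is supplied.
#' @param seed Integer seed.
#' @param grid Named list of candidate values searched by [grid_search()],
#'   e.g. `list(learning_rate = c(0.1, 0.3))`.
#' @return An object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(max_depth = 4, subsample = 1.0,
                            min_child_weight = 2, gamma = 0.8,
                            n_estimators = 200, learning_rate = 0.1,
                            patience = 20, seed = 1L,
                            grid = list(learning_rate = c(0.1, 0.3))) {
  spec <- list(max_depth = as.integer(max_depth), subsample = subsample,
               min_child_weight = min_child_weight, gamma = gamma,
               n_estimators = as.integer(n_estimators),
               learning_rate = learning_rate,
               patience = as.integer(patience), seed = as.integer(seed),
               grid = grid)
  stopifnot(spec$max_depth >= 1, spec$subsample > 0, spec$subsample <= 1,
            spec$min_child_weight >= 0, spec$gamma >= 0,
            spec$n_estimators >= 1, spec$learning_rate > 0)
  structure(spec, class = "classifier_spec")
}

# cheap deterministic checksum of the training data, kept in the model
# metadata so leakage of external rows into training is detectable
data_checksum <- function(features, labels) {
  signif(sum(features * rep_len(c(0.37, 1.13, 0.71), length(features))) +
           sum(labels) * pi + nrow(features), 12)
}

#' Train the boosted-tree link classifier
#'
#' Fits a gradient-boosted decision-tree ensemble (xgboost,
#' `binary:logistic`) on link feature vectors. Training is single-threaded
#' and deterministic under the spec seed. When an evaluation set is given,
#' boosting stops early once its log-loss has not improved for
#' `spec$patience` rounds.
#'
#' @param features Numeric matrix (pairs x `2n`).
#' @param labels Binary 0/1 vector.
#' @param spec A [classifier_spec()].
#' @param eval_set Optional list `list(features =, labels =)` used for early
#'   stopping.
#' @return An object of class `"trained_link_model"`.
#' @export
train_classifier <- function(features, labels, spec = classifier_spec(),
                             eval_set = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("training data contains a single class")
  stopifnot(nrow(features) == length(labels))
  dtrain <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1)
  params <- list(objective = "binary:logistic",
                 max_depth = spec$max_depth, subsample = spec$subsample,
                 min_child_weight = spec$min_child_weight, gamma = spec$gamma,
                 eta = spec$learning_rate, nthread = 1,
                 seed = spec$seed, eval_metric = "logloss")
  if (is.null(eval_set)) {
    booster <- xgboost::xgb.train(params, dtrain, nrounds = spec$n_estimators,
                                  verbose = 0)
    best_iter <- spec$n_estimators
  } else {
    deval <- xgboost::xgb.DMatrix(eval_set$features,
                                  label = as.integer(eval_set$labels),
                                  nthread = 1)
    booster <- xgboost::xgb.train(params, dtrain, nrounds = spec$n_estimators,
                                  evals = list(eval = deval),
                                  early_stopping_rounds = spec$patience,
                                  verbose = 0)
    best_iter <- xgboost::xgb.attr(booster, "best_iteration")
    best_iter <- if (is.null(best_iter)) spec$n_estimators else as.integer(best_iter) + 1L
  }
  model <- structure(
    list(booster = booster, spec = spec, n_features = ncol(features),
         best_iteration = best_iter,
         data_checksum = data_checksum(features, labels)),
    class = "trained_link_model"
  )
  # sanity: the fit must beat the constant predictor on its own training set
  p <- predict(model, features)
  base_rate <- mean(labels)
  ll <- -mean(labels * log(pmax(p, 1e-12)) + (1 - labels) * log(pmax(1 - p, 1e-12)))
  ll0 <- -mean(labels * log(base_rate) + (1 - labels) * log(1 - base_rate))
  if (ll >= ll0) warning("training log-loss does not beat the constant baseline")
  model
}

#' @export
print.trained_link_model <- function(x, ...) {
  cat("<trained_link_model>", x$n_features, "features | depth",
      x$spec$max_depth, "| eta", x$spec$learning_rate, "|",
      x$best_iteration, "rounds\n")
  invisible(x)
}

#' Predict interaction probabilities
#' @param object A `trained_link_model`.
#' @param newdata Feature matrix or [build_features()] result.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.trained_link_model <- function(object, newdata, ...) {
  if (inherits(newdata, "link_feature_set")) newdata <- newdata$features
  if (ncol(newdata) != object$n_features) {
    stop("feature dimension mismatch: model expects ", object$n_features,
         ", got ", ncol(newdata))
  }
  stats::predict(object$booster, xgboost::xgb.DMatrix(newdata, nthread = 1))
}

expand_spec_grid <- function(spec) {
  if (length(spec$grid) == 0) return(list(spec))
  cand <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cand)), function(i) {
    s <- spec
    for (nm in names(cand)) s[[nm]] <- cand[i, nm]
    s$max_depth <- as.integer(s$max_depth)
    s
  })
}

# deterministic candidate ordering: better mean f-beta first, then smaller
# max_depth, then lexicographic over the remaining tunable parameters
order_candidates <- function(scores, specs) {
  keys <- sort(unique(unlist(lapply(specs, function(s) names(s$grid)))))
  keys <- union("max_depth", setdiff(sort(c(keys, "learning_rate", "gamma",
                                            "min_child_weight", "subsample")),
                                     "max_depth"))
  ord_args <- c(list(-round(scores, 12)),
                lapply(keys, function(k) vapply(specs, function(s) as.numeric(s[[k]]), 0)))
  do.call(order, ord_args)
}

#' Grid search over classifier hyperparameters
#'
#' Scores every candidate in the spec's grid by its mean held-out f-beta over
#' the supplied folds and returns the best candidate. Ties are broken by
#' smaller `max_depth`, then lexicographically over the remaining
#' hyperparameters, so candidate ordering never changes the selection.
#'
#' @param features Feature matrix.
#' @param labels Binary labels.
#' @param spec A [classifier_spec()] whose `grid` holds the candidates.
#' @param folds List of test-index vectors partitioning the training rows.
#' @param beta f-beta weight used as the selection metric.
#' @return List with `best_spec`, `scores` (tibble of candidates and mean
#'   f-beta) and, for the best candidate, per-fold `models`, `predictions`
#'   and `metrics`.
#' @export
grid_search <- function(features, labels, spec = classifier_spec(), folds,
                        beta = 1) {
  labels <- as.integer(labels)
  specs <- expand_spec_grid(spec)
  all_rows <- sort(unlist(folds))
  results <- lapply(specs, function(s) {
    fold_fits <- lapply(folds, function(test_idx) {
      train_idx <- setdiff(all_rows, test_idx)
      m <- train_classifier(features[train_idx, , drop = FALSE], labels[train_idx],
                            s, eval_set = list(features = features[test_idx, , drop = FALSE],
                                               labels = labels[test_idx]))
      p <- predict(m, features[test_idx, , drop = FALSE])
      list(model = m, test_idx = test_idx, scores = p,
           metrics = all_metrics(labels[test_idx], p, beta = beta))
    })
    fold_fits
  })
  mean_fbeta <- vapply(results, function(ff) {
    mean(vapply(ff, function(f) f$metrics[["fbeta"]], 0))
  }, 0)
  best <- order_candidates(mean_fbeta, specs)[1]
  scores <- dplyr::bind_rows(lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    tibble::tibble(candidate = i, max_depth = s$max_depth,
                   learning_rate = s$learning_rate, gamma = s$gamma,
                   min_child_weight = s$min_child_weight,
                   subsample = s$subsample, mean_fbeta = mean_fbeta[i],
                   selected = i == best)
  }))
  list(best_spec = specs[[best]], scores = scores, folds = results[[best]])
}
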