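#' Run the repeated cross-validation protocol
#'
#' For each repeat: grid search over the classifier hyperparameters on the
#' internal folds (each candidate trained on a fold's training part, scored
#' on its test part by f-beta), per-fold metrics for the winning candidate,
#' and a single application of the best fold model (highest internal-test
#' f-beta) to the external test set, which never influences training, model
#' selection or early stopping. Finally the winning hyperparameters are
#' refit on all labelled pairs to give the deployable model.
#'
#' @param feature_set A [build_features()] result with labels.
#' @param split A [make_cv_split()] over the same pairs.
#' @param spec A [classifier_spec()].
#' @param beta f-beta weight; `NULL` picks 2 when any negative is sampled
#'   from unknown pairs, otherwise 1.
#' @param threshold Probability threshold for precision/recall.
#' @return An object of class `"dti_cv"` with elements `report` (per
#'   repeat/fold metric tibble), `summary` (mean and sd per metric and
#'   role), `grid_scores`, `best_spec`, `model` (final
#'   `trained_link_model`), `beta`, `threshold`.
#' @export
run_cv <- function(feature_set, split, spec = classifier_spec(), beta = NULL,
                   threshold = 0.5) {
  stopifnot(inherits(feature_set, "link_feature_set"), inherits(split, "cv_split"))
  labels <- feature_set$labels
  if (is.null(labels)) stop("feature set has no labels")
  if (length(labels) != length(split$labels) || !all(labels == split$labels)) {
    stop("split labels disagree with the feature set")
  }
  if (is.null(beta)) {
    prov <- feature_set$pairs[["provenance"]] %||% "validated-negative"
    beta <- if (any(prov == "sampled-unknown-negative")) 2 else 1
  }
  features <- feature_set$features
  ext <- split$external
  rows <- list()
  grid_rows <- list()
  repeat_best <- list()
  for (r in seq_along(split$repeats)) {
    folds <- split$repeats[[r]]
    spec_r <- spec
    spec_r$seed <- child_seed(spec$seed, paste0("cv:", r))
    gs <- grid_search(features, labels, spec_r, folds, beta = beta)
    grid_rows[[r]] <- dplyr::mutate(gs$scores, repeat_ = r, .before = 1)
    fold_fbeta <- vapply(gs$folds, function(f) f$metrics[["fbeta"]], 0)
    for (f in seq_along(gs$folds)) {
      m <- gs$folds[[f]]$metrics
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_ = r, fold = f, role = "internal",
        precision = m[["precision"]], recall = m[["recall"]],
        fbeta = m[["fbeta"]], aupr = m[["aupr"]], auc = m[["auc"]]
      )
    }
    best_fold <- which.max(round(fold_fbeta, 12))
    best_model <- gs$folds[[best_fold]]$model
    # provenance check: the model applied to the external set was trained on
    # internal rows only (its stored training-data checksum must match the
    # checksum recomputed from those rows, which exclude the external set)
    train_rows <- setdiff(sort(unlist(folds)), gs$folds[[best_fold]]$test_idx)
    if (length(intersect(train_rows, ext)) > 0 ||
        !isTRUE(all.equal(best_model$data_checksum,
                          data_checksum(features[train_rows, , drop = FALSE],
                                        labels[train_rows])))) {
      stop("internal error: external test rows leaked into training")
    }
    p_ext <- predict(best_model, features[ext, , drop = FALSE])
    m <- all_metrics(labels[ext], p_ext, beta = beta, threshold = threshold)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      repeat_ = r, fold = NA_integer_, role = "external",
      precision = m[["precision"]], recall = m[["recall"]],
      fbeta = m[["fbeta"]], aupr = m[["aupr"]], auc = m[["auc"]]
    )
    repeat_best[[r]] <- list(spec = gs$best_spec,
                             mean_fbeta = mean(fold_fbeta),
                             best_iters = vapply(gs$folds, function(f) f$model$best_iteration, 0L))
  }
  report <- dplyr::bind_rows(rows)
  grid_scores <- dplyr::bind_rows(grid_rows)
  # winning spec: best mean internal f-beta pooled over repeats
  pooled <- grid_scores |>
    dplyr::group_by(.data$max_depth, .data$learning_rate, .data$gamma,
                    .data$min_child_weight, .data$subsample) |>
    dplyr::summarise(mean_fbeta = mean(.data$mean_fbeta), .groups = "drop") |>
    dplyr::arrange(-round(.data$mean_fbeta, 12), .data$max_depth,
                   .data$learning_rate, .data$gamma, .data$min_child_weight,
                   .data$subsample)
  win <- spec
  for (nm in c("max_depth", "learning_rate", "gamma", "min_child_weight", "subsample")) {
    win[[nm]] <- pooled[[nm]][1]
  }
  win$max_depth <- as.integer(win$max_depth)
  # no held-out data for the final refit: reuse the median early-stopped length
  iters <- unlist(lapply(repeat_best, `[[`, "best_iters"))
  win$n_estimators <- max(1L, as.integer(round(stats::median(iters))))
  win$seed <- child_seed(spec$seed, "cv:final")
  win$grid <- list()
  final <- train_classifier(features, labels, win)
  summary <- report |>
    tidyr::pivot_longer(c("precision", "recall", "fbeta", "aupr", "auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$role, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(report = report, summary = summary, grid_scores = grid_scores,
                 best_spec = win, model = final, beta = beta,
                 threshold = threshold),
            class = "dti_cv")
}

#' @export
print.dti_cv <- function(x, ...) {
  cat("<dti_cv>", max(x$report$repeat_), "repeat(s),",
      sum(x$report$role == "internal") / max(x$report$repeat_),
      "folds | beta =", x$beta, "\n")
  ext <- x$summary[x$summary$role == "external", ]
  for (i in seq_len(nrow(ext))) {
    cat(sprintf("  external %-9s %.4f (sd %.4f)\n", ext$metric[i],
                ext$mean[i], ext$sd[i]))
  }
  invisible(x)
}

#' Tidy a cross-validation result
#' @param x A `dti_cv`.
#' @param ... Unused.
#' @return The per-(repeat, fold) metric tibble (`role` distinguishes
#'   internal folds from the external test set).
#' @export
tidy.dti_cv <- function(x, ...) x$report

#' One-row summary of a cross-validation result
#' @param x A `dti_cv`.
#' @param ... Unused.
#' @return A one-row tibble of external-test means and sds plus the selected
#'   hyperparameters.
#' @export
glance.dti_cv <- function(x, ...) {
  ext <- x$summary[x$summary$role == "external", ]
  out <- tibble::as_tibble(as.list(stats::setNames(ext$mean, ext$metric)))
  sds <- tibble::as_tibble(as.list(stats::setNames(ext$sd, paste0(ext$metric, "_sd"))))
  dplyr::bind_cols(out, sds,
                   tibble::tibble(beta = x$beta,
                                  max_depth = x$best_spec$max_depth,
                                  learning_rate = x$best_spec$learning_rate,
                                  n_rounds = x$best_spec$n_estimators))
}

#' Plot cross-validation metrics
#'
#' One point per repeat/fold and metric, internal folds and the external
#' test separated by colour.
#'
#' @param object A `dti_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dti_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$report,
                              c("precision", "recall", "fbeta", "aupr", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     colour = .data$role)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 95, size = 8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = "Cross-validated link-prediction performance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
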